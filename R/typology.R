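# Nine-type start/end asynchrony typology for binocular fixations.
#
# Offsets are right-eye time minus left-eye time, so a negative start offset
# means the right eye started first and a negative end offset means the left
# eye kept fixating for longer.

ASYNC_LABELS <- c("Syn", "T1", "T2", "T3", "T4", "T5", "T6", "T7", "T8")

.START_CLASSES <- c("sync", "right_early", "left_early")
.END_CLASSES <- c("sync", "left_late", "right_late")

.TYPE_TABLE <- data.frame(
  label = ASYNC_LABELS,
  start_class = c("sync", "sync", "sync",
                  "right_early", "right_early", "right_early",
                  "left_early", "left_early", "left_early"),
  end_class = c("sync", "left_late", "right_late",
                "sync", "left_late", "right_late",
                "sync", "left_late", "right_late"),
  stringsAsFactors = FALSE
)

#' Asynchrony type definitions
#'
#' The nine binocular fixation types form a 3x3 grid over the start-offset
#' class (synchronous, right eye earlier, left eye earlier) and the end-offset
#' class (synchronous, left eye later, right eye later). `Syn` is synchronous
#' on both axes; `T1`-`T8` cover the eight asynchronous cells.
#'
#' @return A data frame with columns `label`, `start_class` and `end_class`,
#'   one row per type.
#' @export
#' @examples
#' asynchrony_types()
asynchrony_types <- function() .TYPE_TABLE

#' Eye-priority groupings of the asynchrony types
#'
#' Types in which one eye starts earlier and/or ends later are grouped by the
#' eye whose input they plausibly prioritise. `T4` and `T8` mix an early
#' advantage for one eye with a late advantage for the other, so their
#' priority is ambiguous and they are conventionally excluded from
#' region-effect modelling.
#'
#' @return A named list of character vectors of type labels:
#'   `left_priority` (`T1`, `T6`, `T7`), `right_priority` (`T2`, `T3`, `T5`),
#'   `early_right`, `early_left`, `late_right`, `late_left`, and `ambiguous`
#'   (`T4`, `T8`).
#' @export
priority_groups <- function() {
  list(
    left_priority = c("T1", "T6", "T7"),
    right_priority = c("T2", "T3", "T5"),
    early_right = c("T3", "T4", "T5"),
    early_left = c("T6", "T7", "T8"),
    late_right = c("T2", "T5", "T8"),
    late_left = c("T1", "T4", "T7"),
    ambiguous = c("T4", "T8")
  )
}

#' Start- and end-time offsets of a binocular fixation
#'
#' The start-time offset is the right eye's fixation start time minus the left
#' eye's; the end-time offset is computed analogously from the end times.
#' Negative start offsets therefore mean the right eye started fixating first.
#'
#' @param pairs A binocular-pair data frame as returned by
#'   [pair_fixations()], with `right_start_ms`/`left_start_ms` (and `_end_ms`)
#'   columns.
#' @return A numeric vector of signed offsets in milliseconds.
#' @export
start_offset <- function(pairs) {
  pairs$right_start_ms - pairs$left_start_ms
}

#' @rdname start_offset
#' @export
end_offset <- function(pairs) {
  pairs$right_end_ms - pairs$left_end_ms
}

#' Classify start/end offsets into the nine asynchrony types
#'
#' An offset within `tol_ms` of zero (inclusive) counts as simultaneous; the
#' default 2 ms tolerance reflects a 500 Hz tracker, where events cannot be
#' resolved more finely than one sample. On the 2 ms grid the synchronous band
#' is exactly \{-2, 0, +2\}.
#'
#' @param start_offset_ms,end_offset_ms Signed offsets in milliseconds
#'   (right-eye time minus left-eye time). Vectors are recycled to a common
#'   length.
#' @param tol_ms Simultaneity tolerance in milliseconds (inclusive); must be
#'   non-negative. Default 2.
#' @param grid_ms Expected sampling grid; offsets that are not multiples of it
#'   are still classified but trigger one warning. Default 2.
#' @return A factor with levels `Syn`, `T1`, ..., `T8`.
#' @export
#' @examples
#' classify_asynchrony(c(0, 0, -4, 4, 4), c(0, -6, 0, 0, 6))
classify_asynchrony <- function(start_offset_ms, end_offset_ms, tol_ms = 2,
                                grid_ms = 2) {
  if (length(tol_ms) != 1L || is.na(tol_ms) || tol_ms < 0) {
    stop("`tol_ms` must be a single non-negative number")
  }
  n <- max(length(start_offset_ms), length(end_offset_ms))
  s <- rep_len(as.numeric(start_offset_ms), n)
  e <- rep_len(as.numeric(end_offset_ms), n)
  if (anyNA(s) || anyNA(e)) stop("offsets must not contain NA")
  if (!is.null(grid_ms) && grid_ms > 0 &&
      any(abs(c(s, e) %% grid_ms) > 1e-9 &
          abs(c(s, e) %% grid_ms - grid_ms) > 1e-9)) {
    warning("some offsets are not multiples of the ", grid_ms,
            " ms sampling grid")
  }
  start_class <- ifelse(abs(s) <= tol_ms, "sync",
                        ifelse(s < -tol_ms, "right_early", "left_early"))
  end_class <- ifelse(abs(e) <= tol_ms, "sync",
                      ifelse(e < -tol_ms, "left_late", "right_late"))
  key <- paste(start_class, end_class)
  lut <- setNames(.TYPE_TABLE$label,
                  paste(.TYPE_TABLE$start_class, .TYPE_TABLE$end_class))
  factor(unname(lut[key]), levels = ASYNC_LABELS)
}

#' Annotate binocular pairs with their asynchrony type
#'
#' Adds (or overwrites) a `type` column computed by [classify_asynchrony()]
#' from the pairs' stored start/end offsets.
#'
#' @inheritParams start_offset
#' @inheritParams classify_asynchrony
#' @return `pairs` with a `type` factor column.
#' @export
classify_pairs <- function(pairs, tol_ms = 2, grid_ms = 2) {
  stopifnot(is.data.frame(pairs))
  pairs$type <- classify_asynchrony(pairs$start_offset_ms,
                                    pairs$end_offset_ms,
                                    tol_ms = tol_ms, grid_ms = grid_ms)
  pairs
}

#' Distribution of asynchrony types
#'
#' Tabulates classified binocular fixations into proportions per type and the
#' standard aggregates: the share of pairs that start synchronously
#' (`Syn + T1 + T2`), end synchronously (`Syn + T3 + T6`), and the
#' left-priority (`T1 + T6 + T7`) and right-priority (`T2 + T3 + T5`) shares.
#'
#' @param types A factor or character vector of type labels, or a data frame
#'   with a `type` column (e.g. from [classify_pairs()]).
#' @return An object of class `binoc_type_distribution`: a list with `counts`
#'   and `proportions` (named over the nine labels), `n`, and `aggregates`.
#' @export
type_distribution <- function(types) {
  if (is.data.frame(types)) {
    if (is.null(types$type)) stop("data frame input must have a `type` column")
    types <- types$type
  }
  if (length(types) == 0L) stop("no classified pairs supplied")
  if (anyNA(types)) stop("unclassified (NA) pairs present")
  types <- factor(as.character(types), levels = ASYNC_LABELS)
  if (anyNA(types)) stop("unknown type labels present")
  counts <- table(types)
  n <- length(types)
  p <- as.numeric(counts) / n
  names(p) <- ASYNC_LABELS
  aggregates <- c(
    start_synchronous = unname(p["Syn"] + p["T1"] + p["T2"]),
    end_synchronous = unname(p["Syn"] + p["T3"] + p["T6"]),
    left_priority = unname(p["T1"] + p["T6"] + p["T7"]),
    right_priority = unname(p["T2"] + p["T3"] + p["T5"])
  )
  structure(
    list(counts = setNames(as.integer(counts), ASYNC_LABELS),
         proportions = p, n = n, aggregates = aggregates),
    class = "binoc_type_distribution"
  )
}

#' @export
print.binoc_type_distribution <- function(x, digits = 3, ...) {
  cat("Asynchrony type distribution (n = ", x$n, " binocular fixations)\n",
      sep = "")
  print(round(100 * x$proportions, digits - 1))
  cat("aggregates (%):\n")
  print(round(100 * x$aggregates, digits - 1))
  invisible(x)
}
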