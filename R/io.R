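# Readers and writers: the canonical per-eye fixation CSV, the EyeLink ASC
# (EFIX/MSG subset) dialect, and the pipeline's CSV/JSON outputs.

CANONICAL_COLUMNS <- c("participant_id", "group", "article_id", "page_id",
                       "eye", "start_ms", "end_ms", "x_px", "y_px")

.sort_fixations <- function(fix) {
  fix <- fix[order(fix$participant_id, fix$eye, fix$start_ms), , drop = FALSE]
  rownames(fix) <- NULL
  fix
}

#' Read per-eye fixation events from the canonical CSV
#'
#' The canonical dialect has one row per monocular fixation with columns
#' `participant_id, group, article_id, page_id, eye, start_ms, end_ms,
#' x_px, y_px` and an optional `blink` flag. Times are integer milliseconds
#' on the tracker grid; fractional times are rejected rather than rounded,
#' since rounding would silently distort the +/-2 ms simultaneity rule.
#' Invalid rows (non-numeric fields, `end <= start`, unknown eye, positions
#' off screen, blink-flagged rows) are dropped and tallied by reason — a
#' missing required column, by contrast, is a hard error.
#'
#' @param path CSV file path.
#' @param screen Optional [screen_geometry()]; when supplied, rows with
#'   positions outside the screen are rejected.
#' @param drop_blinks Drop rows whose optional `blink` column is truthy
#'   (default `TRUE`).
#' @return A validated data frame in canonical column order, sorted by
#'   (participant, eye, start time), with attribute `rejections`: a data
#'   frame of per-reason rejected-row counts.
#' @export
read_fixation_csv <- function(path, screen = NULL, drop_blinks = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character")
  missing_cols <- setdiff(CANONICAL_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  n_in <- nrow(raw)
  reasons <- character(n_in)
  num <- function(x) suppressWarnings(as.numeric(x))
  start_ms <- num(raw$start_ms)
  end_ms <- num(raw$end_ms)
  x_px <- num(raw$x_px)
  y_px <- num(raw$y_px)
  bad_num <- is.na(start_ms) | is.na(end_ms) | is.na(x_px) | is.na(y_px)
  reasons[bad_num] <- "non_numeric"
  frac <- !bad_num & (start_ms != round(start_ms) | end_ms != round(end_ms))
  reasons[frac] <- "fractional_time"
  bad_ord <- !bad_num & !frac & end_ms <= start_ms
  reasons[bad_ord] <- "end_not_after_start"
  bad_eye <- reasons == "" & !(raw$eye %in% c("L", "R"))
  reasons[bad_eye] <- "bad_eye"
  if (!is.null(screen)) {
    stopifnot(inherits(screen, "screen_geometry"))
    off <- reasons == "" &
      (x_px < 0 | x_px > screen$width_px | y_px < 0 | y_px > screen$height_px)
    reasons[off] <- "off_screen"
  }
  if (drop_blinks && !is.null(raw$blink)) {
    bl <- reasons == "" & raw$blink %in% c("1", "TRUE", "true")
    reasons[bl] <- "blink"
  }
  ok <- reasons == ""
  fix <- data.frame(
    participant_id = raw$participant_id[ok], group = raw$group[ok],
    article_id = raw$article_id[ok], page_id = raw$page_id[ok],
    eye = raw$eye[ok], start_ms = start_ms[ok], end_ms = end_ms[ok],
    x_px = x_px[ok], y_px = y_px[ok], stringsAsFactors = FALSE
  )
  rej <- table(reasons[!ok])
  rejections <- data.frame(reason = names(rej), n = as.integer(rej),
                           stringsAsFactors = FALSE)
  if (nrow(rejections)) {
    message("rejected ", sum(rejections$n), "/", n_in, " rows (",
            paste(sprintf("%s: %d", rejections$reason, rejections$n),
                  collapse = "; "), ")")
  }
  fix <- .sort_fixations(fix)
  attr(fix, "rejections") <- rejections
  fix
}

#' Write fixation events to the canonical CSV
#'
#' @param fixations Canonical fixation data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixation_csv <- function(fixations, path) {
  .write_precise(fixations[intersect(c(CANONICAL_COLUMNS, "blink"),
                                     names(fixations))], path)
}

# fixed-precision CSV writer: numeric columns at 3 decimals (lossless for
# tracker-grid times and 0.1 px positions)
.write_precise <- function(df, path, digits = 3) {
  if (nrow(df) == 0L) warning("writing a header-only file: empty collection")
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      v <- round(out[[nm]], digits)
      out[[nm]] <- sub("\\.?0+$", "", formatC(v, format = "f",
                                              digits = digits))
    } else {
      out[[nm]] <- as.character(out[[nm]])
    }
  }
  tryCatch(
    write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("cannot write ", path, ": ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' Read fixation events from an EyeLink ASC export
#'
#' Parses the fixation-report subset of the EyeLink ASCII dialect: `EFIX
#' <eye> <start> <end> <dur> <x> <y> <pupil>` lines, with `MSG` lines whose
#' text starts with `page_message_pattern` delimiting pages. The message text
#' may carry one token (`<pattern> <page>`) or two (`<pattern> <article>
#' <page>`); with none, pages are numbered sequentially. Fixations occurring
#' before the first page message are dropped and counted; malformed `EFIX`
#' lines are skipped and counted.
#'
#' @param path ASC file path.
#' @param page_message_pattern Literal prefix of page-delimiting `MSG` lines
#'   (default `"PAGE"`).
#' @param participant_id Participant label; defaults to the file name without
#'   extension.
#' @param group Group label stamped on all events.
#' @return A canonical fixation data frame (see [read_fixation_csv()]) with
#'   attribute `rejections`.
#' @export
read_eyelink_asc <- function(path, page_message_pattern = "PAGE",
                             participant_id = NULL, group = "all") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  article <- "A01"
  page <- NA_character_
  page_counter <- 0L
  rows <- list()
  n_skipped <- 0L
  n_before_page <- 0L
  msg_re <- "^MSG\\s+\\d+\\s+(.*)$"
  for (ln in lines) {
    if (grepl("^MSG", ln)) {
      txt <- trimws(sub(msg_re, "\\1", ln))
      if (startsWith(txt, page_message_pattern)) {
        toks <- strsplit(trimws(substring(txt,
                                          nchar(page_message_pattern) + 1)),
                         "\\s+")[[1]]
        toks <- toks[nzchar(toks)]
        page_counter <- page_counter + 1L
        if (length(toks) >= 2) {
          article <- toks[1]
          page <- toks[2]
        } else if (length(toks) == 1) {
          page <- toks[1]
        } else {
          page <- sprintf("pg%02d", page_counter)
        }
      }
    } else if (grepl("^EFIX", ln)) {
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(toks) < 7) {
        n_skipped <- n_skipped + 1L
        next
      }
      eye <- toks[2]
      v <- suppressWarnings(as.numeric(toks[3:7]))
      if (!(eye %in% c("L", "R")) || anyNA(v[1:2]) || anyNA(v[4:5]) ||
          v[2] <= v[1]) {
        n_skipped <- n_skipped + 1L
        next
      }
      if (is.na(page)) {
        n_before_page <- n_before_page + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = participant_id, group = group,
        article_id = article, page_id = page, eye = eye,
        start_ms = v[1], end_ms = v[2], x_px = v[4], y_px = v[5],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) stop("no parseable EFIX lines in ", path)
  fix <- .sort_fixations(do.call(rbind, rows))
  rejections <- data.frame(
    reason = c("malformed_efix", "outside_page"),
    n = c(n_skipped, n_before_page), stringsAsFactors = FALSE
  )
  rejections <- rejections[rejections$n > 0, , drop = FALSE]
  if (nrow(rejections)) {
    message("skipped ", sum(rejections$n), " records (",
            paste(sprintf("%s: %d", rejections$reason, rejections$n),
                  collapse = "; "), ")")
  }
  attr(fix, "rejections") <- rejections
  fix
}

#' Write pipeline outputs
#'
#' `write_pairs_csv()` and `write_counts_csv()` write binocular pairs and
#' count records with a deterministic column order and fixed numeric
#' precision, so files round-trip losslessly at that precision.
#' `write_fit_json()` serialises a fit result (or any list-like report) to
#' JSON at full precision.
#'
#' @param pairs,counts,fit Objects from [pair_fixations()], [count_table()]
#'   and the model-fitting functions.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pairs_csv <- function(pairs, path) {
  cols <- c("participant_id", "group", "article_id", "page_id",
            "left_start_ms", "left_end_ms", "left_x_px", "left_y_px",
            "right_start_ms", "right_end_ms", "right_x_px", "right_y_px",
            "start_offset_ms", "end_offset_ms", "overlap_ms",
            "x_px", "y_px", "type", "region")
  out <- pairs[intersect(cols, names(pairs))]
  .write_precise(out, path)
}

#' @rdname write_pairs_csv
#' @export
write_counts_csv <- function(counts, path) {
  .write_precise(
    counts[c("participant_id", "group", "article_id", "page_id",
             "region", "type", "count")], path)
}

#' @rdname write_pairs_csv
#' @export
write_fit_json <- function(fit, path) {
  tryCatch(
    jsonlite::write_json(unclass_deep(fit), path, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns", null = "null"),
    error = function(e) stop("cannot write ", path, ": ",
                             conditionMessage(e))
  )
  invisible(path)
}

# strip S3 classes recursively so jsonlite writes plain structures
unclass_deep <- function(x) {
  if (is.data.frame(x)) {
    as.list(as.data.frame(lapply(x, function(col) {
      if (is.factor(col)) as.character(col) else col
    }), stringsAsFactors = FALSE))
  } else if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else if (is.factor(x)) {
    as.character(x)
  } else {
    x
  }
}
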