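# Pairing of the two eyes' monocular fixation streams into binocular
# fixations: temporally overlapping left/right events matched one-to-one.

#' Temporal overlap between two intervals
#'
#' Overlap is `max(0, min(ends) - max(starts))`; a shared endpoint is not
#' overlap. All arguments are vectorised.
#'
#' @param start_a,end_a,start_b,end_b Interval bounds in milliseconds.
#' @return Non-negative overlap durations in milliseconds.
#' @export
#' @examples
#' temporal_overlap(0, 200, 150, 400) # 50
#' temporal_overlap(0, 100, 100, 200) # 0: touching intervals do not overlap
temporal_overlap <- function(start_a, end_a, start_b, end_b) {
  pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
}

.session_key <- function(fix) {
  paste(fix$participant_id, fix$article_id, fix$page_id, sep = "\r")
}

.check_stream <- function(fix, eye, where) {
  if (nrow(fix) == 0L) return(invisible(NULL))
  if (!all(fix$eye == eye)) {
    stop("stream passed as the ", eye, " eye contains other-eye events (",
         where, ")")
  }
  if (is.unsorted(fix$start_ms)) {
    stop(eye, " stream is not sorted by start time (", where, ")")
  }
  n <- nrow(fix)
  if (n > 1L && any(fix$start_ms[-1] < fix$end_ms[-n])) {
    stop(eye, " stream has temporally overlapping fixations within one eye (",
         where, ")")
  }
  invisible(NULL)
}

#' Pair left- and right-eye fixation streams into binocular fixations
#'
#' Finds, independently within each (participant, article, page) session, the
#' one-to-one non-crossing matching of left- to right-eye fixations that
#' maximises total temporal overlap, by dynamic programming over the two
#' sorted streams. Only pairs with strictly positive overlap are formed; each
#' monocular fixation is used at most once, and matched pairs never cross in
#' time (the k-th matched left fixation goes with the k-th matched right
#' fixation). Ties in total overlap are broken toward the earlier right
#' fixation.
#'
#' @param left,right Data frames of monocular fixations in the canonical
#'   layout (see [read_fixation_csv()]): columns `participant_id`, `group`,
#'   `article_id`, `page_id`, `eye`, `start_ms`, `end_ms`, `x_px`, `y_px`.
#'   Each stream must be sorted by start time and internally non-overlapping
#'   within every session; violations are an error.
#' @return A data frame of binocular fixations with one row per matched pair:
#'   session labels, the left and right eyes' times and positions
#'   (`left_start_ms`, ..., `right_y_px`), `start_offset_ms`, `end_offset_ms`
#'   (right minus left), `overlap_ms`, and the pair position `x_px`, `y_px`
#'   (the right eye's mean coordinates). The attribute `unpaired` holds the
#'   per-eye counts of fixations left unmatched.
#' @seealso [classify_pairs()], [assign_region()]
#' @export
pair_fixations <- function(left, right) {
  stopifnot(is.data.frame(left), is.data.frame(right))
  keys <- union(unique(.session_key(left)), unique(.session_key(right)))
  lk <- .session_key(left)
  rk <- .session_key(right)
  out <- vector("list", length(keys))
  unpaired <- c(left = 0L, right = 0L)
  for (ki in seq_along(keys)) {
    key <- keys[ki]
    l <- left[lk == key, , drop = FALSE]
    r <- right[rk == key, , drop = FALSE]
    .check_stream(l, "L", key)
    .check_stream(r, "R", key)
    if (nrow(l) == 0L || nrow(r) == 0L) {
      unpaired <- unpaired + c(left = nrow(l), right = nrow(r))
      next
    }
    m <- pair_dp_cpp(l$start_ms, l$end_ms, r$start_ms, r$end_ms)
    unpaired <- unpaired +
      c(left = nrow(l) - nrow(m), right = nrow(r) - nrow(m))
    if (nrow(m) == 0L) next
    li <- m[, 1]
    rj <- m[, 2]
    out[[ki]] <- data.frame(
      participant_id = l$participant_id[li],
      group = l$group[li],
      article_id = l$article_id[li],
      page_id = l$page_id[li],
      left_start_ms = l$start_ms[li],
      left_end_ms = l$end_ms[li],
      left_x_px = l$x_px[li],
      left_y_px = l$y_px[li],
      right_start_ms = r$start_ms[rj],
      right_end_ms = r$end_ms[rj],
      right_x_px = r$x_px[rj],
      right_y_px = r$y_px[rj],
      stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(pairs)) {
    pairs <- data.frame(
      participant_id = character(), group = character(),
      article_id = character(), page_id = character(),
      left_start_ms = numeric(), left_end_ms = numeric(),
      left_x_px = numeric(), left_y_px = numeric(),
      right_start_ms = numeric(), right_end_ms = numeric(),
      right_x_px = numeric(), right_y_px = numeric(),
      stringsAsFactors = FALSE
    )
  }
  pairs$start_offset_ms <- pairs$right_start_ms - pairs$left_start_ms
  pairs$end_offset_ms <- pairs$right_end_ms - pairs$left_end_ms
  pairs$overlap_ms <- temporal_overlap(pairs$left_start_ms, pairs$left_end_ms,
                                       pairs$right_start_ms,
                                       pairs$right_end_ms)
  pairs$x_px <- pairs$right_x_px
  pairs$y_px <- pairs$right_y_px
  pairs <- pairs[order(pairs$participant_id, pairs$article_id, pairs$page_id,
                       pairs$left_start_ms), , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "unpaired") <- unpaired
  pairs
}
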