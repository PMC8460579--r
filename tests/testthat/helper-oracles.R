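# Independent oracles and fixture builders used across the suite.

# Brute-force typology oracle: coded directly from the class definitions,
# independently of the package's lookup table.
oracle_classify <- function(s, e, tol = 2) {
  stopifnot(length(s) == 1, length(e) == 1)
  if (abs(s) <= tol) {
    if (abs(e) <= tol) return("Syn")
    if (e < -tol) return("T1") # synchronous start, left eye fixates longer
    return("T2")               # synchronous start, right eye fixates longer
  }
  if (s < -tol) {              # right eye starts earlier
    if (abs(e) <= tol) return("T3")
    if (e < -tol) return("T4")
    return("T5")
  }
  # left eye starts earlier
  if (abs(e) <= tol) return("T6")
  if (e < -tol) return("T7")
  "T8"
}

# Exhaustive-enumeration oracle for the pairing problem: maximum total
# overlap over all one-to-one NON-CROSSING matchings, by recursion over the
# two streams (memoised would be the DP itself, so keep it plainly recursive
# and only use it on small instances).
oracle_match_value <- function(ls, le, rs, re) {
  rec <- function(i, j) {
    if (i > length(ls) || j > length(rs)) return(0)
    best <- max(rec(i + 1, j), rec(i, j + 1))
    w <- min(le[i], re[j]) - max(ls[i], rs[j])
    if (w > 0) best <- max(best, w + rec(i + 1, j + 1))
    best
  }
  rec(1, 1)
}

# Greedy reference matcher: repeatedly take the largest-overlap available
# pair (ignoring the non-crossing constraint when scanning, but a greedy
# max-overlap pick can never cross itself into a larger total).
greedy_match_value <- function(ls, le, rs, re) {
  used_l <- rep(FALSE, length(ls))
  used_r <- rep(FALSE, length(rs))
  total <- 0
  repeat {
    best_w <- 0
    bi <- bj <- 0
    for (i in seq_along(ls)[!used_l]) {
      for (j in seq_along(rs)[!used_r]) {
        w <- min(le[i], re[j]) - max(ls[i], rs[j])
        if (w > best_w) {
          best_w <- w
          bi <- i
          bj <- j
        }
      }
    }
    if (best_w <= 0) break
    used_l[bi] <- TRUE
    used_r[bj] <- TRUE
    total <- total + best_w
  }
  total
}

# random non-overlapping sorted fixation stream on the integer-ms grid
random_stream <- function(n, max_dur = 20) {
  gaps <- 2 * sample(1:max_dur, n, replace = TRUE)
  durs <- 2 * sample(1:max_dur, n, replace = TRUE)
  starts <- cumsum(gaps + c(0, durs[-n]))
  list(start = starts, end = starts + durs)
}

# canonical monocular fixation data frame builder
make_fix <- function(start, end, eye = "L", x = 500, y = 400,
                     participant = "P01", article = "A01", page = "pg01",
                     group = "test") {
  n <- length(start)
  data.frame(
    participant_id = rep_len(participant, n), group = rep_len(group, n),
    article_id = rep_len(article, n), page_id = rep_len(page, n),
    eye = rep_len(eye, n), start_ms = start, end_ms = end,
    x_px = rep_len(x, n), y_px = rep_len(y, n), stringsAsFactors = FALSE
  )
}

# Write a canonical fixation data frame as an EyeLink-style ASC export:
# one PAGE message per (article, page), then that page's EFIX lines in
# start-time order.
write_asc_fixture <- function(fix, path, pattern = "PAGE") {
  lines <- c("** synthetic ASC fixture")
  keys <- unique(fix[c("article_id", "page_id")])
  keys <- keys[order(keys$article_id, keys$page_id), , drop = FALSE]
  for (k in seq_len(nrow(keys))) {
    sub <- fix[fix$article_id == keys$article_id[k] &
                 fix$page_id == keys$page_id[k], , drop = FALSE]
    sub <- sub[order(sub$start_ms), , drop = FALSE]
    t0 <- min(sub$start_ms)
    lines <- c(lines, sprintf("MSG\t%d %s %s %s", t0, pattern,
                              keys$article_id[k], keys$page_id[k]))
    lines <- c(lines, sprintf("EFIX %s   %d\t%d\t%d\t  %.1f\t  %.1f\t  512",
                              sub$eye, sub$start_ms, sub$end_ms,
                              sub$end_ms - sub$start_ms, sub$x_px, sub$y_px))
  }
  writeLines(lines, path)
  invisible(path)
}

# small classified+regioned pair frame used by count-table tests
toy_pairs <- function() {
  p <- data.frame(
    participant_id = c("P01", "P01", "P01", "P02", "P02", "P02"),
    group = "test",
    article_id = "A01",
    page_id = c("pg01", "pg01", "pg01", "pg01", "pg01", "pg02"),
    x_px = c(100, 150, 120, 600, 900, 950),
    y_px = 400,
    type = c("Syn", "Syn", "Syn", "T3", "T6", "T6"),
    stringsAsFactors = FALSE
  )
  p$region <- assign_region(p$x_px, screen_geometry())
  p
}

fast_glmm_control <- function() {
  lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE)
}
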