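# Synthetic binocular reading generator.
#
# Emulates 500 Hz-quantized per-eye fixation streams over multi-line pages:
# a left-to-right fixation walk along each text line with a return sweep
# between lines, each conceptual fixation spawning one left-eye and one
# right-eye event separated by long-tailed (Laplace) start/end lags whose
# location drifts linearly with horizontal position.

#' Laplace (two-sided exponential) random draws
#'
#' @param n Number of draws.
#' @param location,scale Location and scale parameters; `scale > 0`.
#' @return Numeric vector.
#' @keywords internal
rlaplace <- function(n, location = 0, scale = 1) {
  stopifnot(all(scale > 0))
  u <- runif(n) - 0.5
  location - scale * sign(u) * log(1 - 2 * abs(u))
}

# Round to multiples of q, halves away from zero (so the offset lattice is
# symmetric about 0).
.quantize <- function(t, q) {
  q * sign(t) * floor(abs(t) / q + 0.5)
}

#' Configuration for the synthetic binocular reading generator
#'
#' The defaults emulate the kind of study the pipeline is built for: 36
#' participants reading 21 short articles of about five pages with up to five
#' left-justified lines per page on a 1024 x 768 display, tracked at 500 Hz
#' (2 ms quantum). Per-eye start/end lags are long-tailed (Laplace) with a
#' single-digit-millisecond scale, and their location drifts linearly with
#' horizontal position so that the right eye tends to start earlier / end
#' later toward the right of a line and the left eye toward the left.
#'
#' @param n_participants,n_articles,pages_per_article Design counts, all >= 1.
#' @param lines_per_page Text lines per page, at most 5.
#' @param line_length_px Usable line length in pixels, at most the screen
#'   width.
#' @param screen A [screen_geometry()].
#' @param fixdur_log_mean,fixdur_log_sd Log-normal fixation-duration
#'   parameters (log-milliseconds); defaults give a median of ~225 ms.
#' @param saccade_ms Inter-fixation gap in milliseconds.
#' @param saccade_len_px Mean rightward saccade amplitude in pixels.
#' @param lag_scale_ms Laplace scale of the start/end offset distributions
#'   (milliseconds), > 0.
#' @param start_bias_slope,end_bias_slope Location shift of the start/end
#'   offset distribution, in ms per unit of normalized horizontal position
#'   `u = 2 x / width - 1`. Positive slopes plant right-eye priority (earlier
#'   start, later end) at the right of the screen and left-eye priority at
#'   the left.
#' @param sweep_advance_ms Additional left-eye start advantage (ms) on the
#'   first fixation after a return sweep, reflecting the left eye's faster
#'   abducting travel on right-to-left sweeps. Set 0 to disable.
#' @param forward_advance_ms Right-eye start advantage (ms) on all other
#'   (left-to-right) fixations: on forward saccades the abducting right eye
#'   tends to arrive first. Makes right-priority types outnumber
#'   left-priority ones overall. Set 0 to disable.
#' @param quantum_ms Sampling quantum; all emitted times are multiples of it.
#'   Default 2 (500 Hz).
#' @param max_bad_frac Largest tolerated fraction of conceptual fixations
#'   whose lag perturbation would make one eye's duration non-positive;
#'   beyond it the configuration is rejected as degenerate.
#' @param group Group label stamped on all events.
#' @param seed Integer seed; all sub-streams are derived from it via stable
#'   per-page seeding, so identical configurations reproduce identical
#'   streams.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 36, n_articles = 21,
                       pages_per_article = 5, lines_per_page = 5,
                       line_length_px = 900, screen = screen_geometry(),
                       fixdur_log_mean = log(225), fixdur_log_sd = 0.35,
                       saccade_ms = 30, saccade_len_px = 100,
                       lag_scale_ms = 1.5,
                       start_bias_slope = 3, end_bias_slope = 3,
                       sweep_advance_ms = 4, forward_advance_ms = 1,
                       quantum_ms = 2,
                       max_bad_frac = 0.01, group = "sim", seed = 1) {
  stopifnot(inherits(screen, "screen_geometry"))
  counts <- c(n_participants, n_articles, pages_per_article, lines_per_page)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("design counts must be integers >= 1")
  }
  if (lines_per_page > 5) stop("at most 5 lines per page")
  if (line_length_px <= 0 || line_length_px > screen$width_px) {
    stop("line length must be positive and fit on the screen")
  }
  if (lag_scale_ms <= 0) stop("lag_scale_ms must be > 0")
  if (quantum_ms <= 0) stop("quantum_ms must be > 0")
  if (saccade_ms <= 0 || saccade_len_px <= 0) {
    stop("saccade parameters must be positive")
  }
  if (max_bad_frac < 0 || max_bad_frac >= 1) {
    stop("max_bad_frac must be in [0, 1)")
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_articles = as.integer(n_articles),
         pages_per_article = as.integer(pages_per_article),
         lines_per_page = as.integer(lines_per_page),
         line_length_px = line_length_px, screen = screen,
         fixdur_log_mean = fixdur_log_mean, fixdur_log_sd = fixdur_log_sd,
         saccade_ms = saccade_ms, saccade_len_px = saccade_len_px,
         lag_scale_ms = lag_scale_ms,
         start_bias_slope = start_bias_slope,
         end_bias_slope = end_bias_slope,
         sweep_advance_ms = sweep_advance_ms,
         forward_advance_ms = forward_advance_ms, quantum_ms = quantum_ms,
         max_bad_frac = max_bad_frac, group = group,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Stable sub-stream seed per (participant, article, page); keeps partial
# regeneration reproducible under one global seed.
.page_seed <- function(seed, p, a, pg) {
  as.integer((as.numeric(seed) * 7919 + p * 104729 + a * 1009 + pg * 97) %%
               2147483647)
}

#' Simulate a binocular reading session
#'
#' Generates left- and right-eye fixation event streams for every
#' participant, article and page in `config`. Each page is a left-to-right
#' fixation walk along each line with a return sweep between lines. A
#' conceptual fixation at horizontal position `x` (normalized
#' `u = 2 x / width - 1`) draws a start offset from
#' `Laplace(-start_bias_slope * u, lag_scale_ms)` and an end offset from
#' `Laplace(+end_bias_slope * u, lag_scale_ms)`; each offset is split half
#' and half between the two eyes as signed lags around the base times, so the
#' emitted right-minus-left offsets follow the planted Laplace law exactly
#' (before quantization). All times are then rounded to the `quantum_ms` grid
#' (halves away from zero), which confines offsets to the even-millisecond
#' lattice at the default 2 ms quantum.
#'
#' Conceptual fixations whose perturbed duration would be non-positive in
#' either eye are dropped (both eyes); if their fraction exceeds
#' `max_bad_frac` the configuration is rejected as degenerate. The rare
#' fixation that would overlap its predecessor within one eye after
#' perturbation is also dropped from both streams, preserving intra-eye
#' temporal order.
#'
#' @param config A [sim_config()].
#' @return A list of class `binoc_sim` with elements `left` and `right`
#'   (canonical fixation data frames, sorted by participant and start time)
#'   and `truth`, which stores the planted parameters exactly as used
#'   (bias slopes, sweep advance, lag scale) plus per-fixation raw
#'   (pre-quantization) offsets and the drop tallies.
#' @export
simulate_reading_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sc <- config$screen
  width <- sc$width_px
  line_y <- 100 + 120 * (seq_len(config$lines_per_page) - 1)
  x0 <- 60
  page_span <- 60000
  if (x0 + config$line_length_px > width) {
    stop("line does not fit on the screen with the left margin")
  }
  res_l <- list()
  res_r <- list()
  raw <- list()
  n_bad_dur <- 0L
  n_bad_order <- 0L
  n_total <- 0L
  idx <- 0L
  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", p)
    for (a in seq_len(config$n_articles)) {
      aid <- sprintf("A%02d", a)
      for (pg in seq_len(config$pages_per_article)) {
        set.seed(.page_seed(config$seed, p, a, pg))
        page0 <- ((a - 1) * config$pages_per_article + (pg - 1)) * page_span
        xs <- numeric(0)
        ys <- numeric(0)
        sweep <- logical(0)
        for (line in seq_len(config$lines_per_page)) {
          x <- x0 + runif(1, 0, 0.3 * config$saccade_len_px)
          first <- TRUE
          while (x <= x0 + config$line_length_px) {
            xs <- c(xs, x)
            ys <- c(ys, line_y[line] + runif(1, -5, 5))
            sweep <- c(sweep, first && line > 1)
            first <- FALSE
            step <- rnorm(1, config$saccade_len_px,
                          0.25 * config$saccade_len_px)
            x <- x + max(step, 0.3 * config$saccade_len_px)
          }
        }
        nf <- length(xs)
        if (nf == 0L) next
        n_total <- n_total + nf
        dur <- rlnorm(nf, config$fixdur_log_mean, config$fixdur_log_sd)
        gaps <- config$saccade_ms * ifelse(sweep, 2, 1)
        incr <- if (nf > 1L) dur[-nf] + gaps[-1] else numeric(0)
        t_start <- page0 + 1000 + cumsum(c(0, incr))
        t_end <- t_start + dur
        u <- 2 * xs / width - 1
        loc_s <- -config$start_bias_slope * u +
          ifelse(sweep, config$sweep_advance_ms, -config$forward_advance_ms)
        loc_e <- config$end_bias_slope * u
        d_s <- rlaplace(nf, loc_s, config$lag_scale_ms)
        d_e <- rlaplace(nf, loc_e, config$lag_scale_ms)
        ls <- .quantize(t_start - d_s / 2, config$quantum_ms)
        le <- .quantize(t_end - d_e / 2, config$quantum_ms)
        rs <- .quantize(t_start + d_s / 2, config$quantum_ms)
        re <- .quantize(t_end + d_e / 2, config$quantum_ms)
        bad <- le <= ls | re <= rs
        n_bad_dur <- n_bad_dur + sum(bad)
        keep <- which(!bad)
        # drop (rare) fixations that would overlap their kept predecessor
        # within either eye, preserving strict intra-eye temporal order
        kept <- integer(0)
        last_le <- -Inf
        last_re <- -Inf
        for (k in keep) {
          if (ls[k] >= last_le && rs[k] >= last_re) {
            kept <- c(kept, k)
            last_le <- le[k]
            last_re <- re[k]
          } else {
            n_bad_order <- n_bad_order + 1L
          }
        }
        if (length(kept) == 0L) next
        idx <- idx + 1L
        xq <- round(xs[kept], 1)
        yq <- round(ys[kept], 1)
        base <- data.frame(
          participant_id = pid, group = config$group, article_id = aid,
          page_id = sprintf("pg%02d", pg), stringsAsFactors = FALSE
        )[rep(1, length(kept)), , drop = FALSE]
        res_l[[idx]] <- cbind(base, eye = "L", start_ms = ls[kept],
                              end_ms = le[kept], x_px = xq, y_px = yq)
        res_r[[idx]] <- cbind(base, eye = "R", start_ms = rs[kept],
                              end_ms = re[kept], x_px = xq, y_px = yq)
        raw[[idx]] <- data.frame(u = u[kept], start_offset = d_s[kept],
                                 end_offset = d_e[kept], sweep = sweep[kept])
      }
    }
  }
  if (n_total > 0 && n_bad_dur / n_total > config$max_bad_frac) {
    stop("degenerate configuration: ",
         sprintf("%.1f%%", 100 * n_bad_dur / n_total),
         " of fixations had non-positive perturbed durations (limit ",
         sprintf("%.1f%%", 100 * config$max_bad_frac), ")")
  }
  left <- do.call(rbind, res_l)
  right <- do.call(rbind, res_r)
  ord <- order(left$participant_id, left$start_ms)
  left <- left[ord, , drop = FALSE]
  ord <- order(right$participant_id, right$start_ms)
  right <- right[ord, , drop = FALSE]
  rownames(left) <- NULL
  rownames(right) <- NULL
  truth <- list(
    start_bias_slope = config$start_bias_slope,
    end_bias_slope = config$end_bias_slope,
    sweep_advance_ms = config$sweep_advance_ms,
    forward_advance_ms = config$forward_advance_ms,
    lag_scale_ms = config$lag_scale_ms,
    quantum_ms = config$quantum_ms,
    raw_offsets = do.call(rbind, raw),
    n_dropped_duration = n_bad_dur,
    n_dropped_order = n_bad_order,
    n_conceptual = n_total
  )
  structure(list(left = left, right = right, truth = truth, config = config),
            class = "binoc_sim")
}

#' Simulate a ready-made count table with planted effects
#'
#' Fast path for validating the count models without running the full
#' event-level pipeline: counts per (participant, article, page, region) cell
#' are drawn Poisson with
#' `log(mean) = intercept + region effect + participant + article + page`
#' random intercepts, the random intercepts normal with the stated standard
#' deviations.
#'
#' @param planted_effects Named numeric: log rate ratios `left` and `right`
#'   versus the middle region.
#' @param grouping_sds Named numeric standard deviations (>= 0) for the
#'   `participant`, `article` and `page` random intercepts.
#' @param n_participants,n_articles,pages_per_article Design counts.
#' @param intercept Log mean count of the middle region for an average unit.
#' @param type_label Type label stamped on the records.
#' @param seed Integer seed; draws are deterministic per seed.
#' @return A count-record data frame (as from [count_table()]) with a
#'   `truth` attribute storing the planted effects, SDs, intercept and the
#'   drawn random intercepts exactly as used.
#' @export
simulate_count_table <- function(planted_effects = c(left = 0.46,
                                                     right = -0.13),
                                 grouping_sds = c(participant = 0.23,
                                                  article = 0.08,
                                                  page = 0.13),
                                 n_participants = 36, n_articles = 7,
                                 pages_per_article = 5,
                                 intercept = 0.56, type_label = "T6",
                                 seed = 1) {
  stopifnot(all(is.finite(planted_effects)),
            all(c("left", "right") %in% names(planted_effects)))
  sds <- c(participant = 0, article = 0, page = 0)
  sds[names(grouping_sds)] <- grouping_sds
  if (any(sds < 0)) stop("grouping SDs must be >= 0")
  set.seed(as.integer(seed))
  pids <- sprintf("P%02d", seq_len(n_participants))
  aids <- sprintf("A%02d", seq_len(n_articles))
  pgs <- sprintf("pg%02d", seq_len(pages_per_article))
  b_part <- setNames(rnorm(n_participants, 0, sds["participant"]), pids)
  b_art <- setNames(rnorm(n_articles, 0, sds["article"]), aids)
  page_keys <- as.vector(outer(aids, pgs, paste, sep = ":"))
  b_page <- setNames(rnorm(length(page_keys), 0, sds["page"]), page_keys)
  grid <- expand.grid(region = c("left", "middle", "right"),
                      page_id = pgs, article_id = aids,
                      participant_id = pids, stringsAsFactors = FALSE)
  eff <- c(left = unname(planted_effects["left"]), middle = 0,
           right = unname(planted_effects["right"]))
  pk <- paste(grid$article_id, grid$page_id, sep = ":")
  lmu <- intercept + eff[grid$region] + b_part[grid$participant_id] +
    b_art[grid$article_id] + b_page[pk]
  counts <- rpois(nrow(grid), exp(lmu))
  out <- data.frame(
    participant_id = grid$participant_id, group = "sim",
    article_id = grid$article_id, page_id = grid$page_id,
    region = factor(grid$region, levels = c("left", "middle", "right")),
    type = type_label, count = counts, stringsAsFactors = FALSE
  )
  out <- out[order(out$participant_id, out$article_id, out$page_id,
                   out$region), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    planted_effects = planted_effects, grouping_sds = sds,
    intercept = intercept,
    ranef = list(participant = b_part, article = b_art, page = b_page)
  )
  out
}
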