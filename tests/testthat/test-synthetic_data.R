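# The synthetic binocular reading generator: determinism, grid and ordering
# contracts, and the planted lag model.

small_cfg <- function(seed = 11, ...) {
  sim_config(n_participants = 2, n_articles = 2, pages_per_article = 2,
             seed = seed, ...)
}

test_that("the generator is deterministic and reproducible per seed", {
  s1 <- simulate_reading_session(small_cfg())
  s2 <- simulate_reading_session(small_cfg())
  expect_identical(s1$left, s2$left)
  expect_identical(s1$right, s2$right)
  expect_identical(s1$truth$raw_offsets, s2$truth$raw_offsets)
  s3 <- simulate_reading_session(small_cfg(seed = 12))
  expect_false(identical(s1$left, s3$left))
})

test_that("emitted times sit on the quantum grid, non-negative and ordered", {
  s <- simulate_reading_session(small_cfg())
  for (st in list(s$left, s$right)) {
    expect_true(all(st$start_ms >= 0))
    expect_true(all(st$start_ms %% 2 == 0))
    expect_true(all(st$end_ms %% 2 == 0))
    expect_true(all(st$end_ms > st$start_ms))
    for (pid in unique(st$participant_id)) {
      sub <- st[st$participant_id == pid, ]
      expect_false(is.unsorted(sub$start_ms))
      expect_true(all(sub$start_ms[-1] >= sub$end_ms[-nrow(sub)]))
    }
    expect_true(all(st$x_px >= 0 & st$x_px <= 1024))
    expect_true(all(st$y_px >= 0 & st$y_px <= 768))
  }
})

test_that("the no-noise limit yields perfectly synchronous pairs", {
  cfg <- small_cfg(lag_scale_ms = 1e-9, start_bias_slope = 0,
                   end_bias_slope = 0, sweep_advance_ms = 0,
                   forward_advance_ms = 0)
  s <- simulate_reading_session(cfg)
  p <- pair_fixations(s$left, s$right)
  expect_equal(nrow(p), nrow(s$left))
  expect_true(all(p$start_offset_ms == 0))
  expect_true(all(p$end_offset_ms == 0))
  d <- type_distribution(classify_pairs(p))
  expect_equal(d$proportions[["Syn"]], 1)
})

test_that("zero bias gives offsets symmetric about zero", {
  cfg <- sim_config(n_participants = 12, n_articles = 5,
                    pages_per_article = 4, start_bias_slope = 0,
                    end_bias_slope = 0, sweep_advance_ms = 0,
                    forward_advance_ms = 0, seed = 21)
  s <- simulate_reading_session(cfg)
  p <- pair_fixations(s$left, s$right)
  expect_gt(nrow(p), 1e4)
  for (off in list(p$start_offset_ms, p$end_offset_ms)) {
    nz <- off[off != 0]
    pv <- binom.test(sum(nz > 0), length(nz))$p.value
    expect_gt(pv, 0.01)
  }
})

test_that("offset magnitudes follow the planted Laplace scale", {
  # large scale and long durations/gaps so that neither quantization nor the
  # duration/order guards distort the planted law
  cfg <- sim_config(n_participants = 12, n_articles = 5,
                    pages_per_article = 4, lag_scale_ms = 40,
                    fixdur_log_mean = log(500), saccade_ms = 250,
                    start_bias_slope = 0, end_bias_slope = 0,
                    sweep_advance_ms = 0, forward_advance_ms = 0, seed = 22)
  s <- simulate_reading_session(cfg)
  raw <- s$truth$raw_offsets
  expect_gt(nrow(raw), 1e4)
  # raw (pre-quantization) offsets: exact Laplace law
  expect_equal(median(abs(raw$start_offset)), 40 * log(2),
               tolerance = 0.1)
  # emitted streams: same law up to the 2 ms lattice
  p <- pair_fixations(s$left, s$right)
  expect_equal(median(abs(p$start_offset_ms)) / (40 * log(2)), 1,
               tolerance = 0.1)
})

test_that("a planted start bias shifts right-eye-first rates across regions,
           with the sign the Laplace location model predicts", {
  cfg <- sim_config(n_participants = 12, n_articles = 5,
                    pages_per_article = 4, start_bias_slope = 6,
                    end_bias_slope = 0, sweep_advance_ms = 0,
                    forward_advance_ms = 0, seed = 23)
  s <- simulate_reading_session(cfg)
  p <- pair_fixations(s$left, s$right)
  expect_gt(nrow(p), 1e4)
  region <- assign_region(p$x_px, cfg$screen)
  r_first <- p$start_offset_ms < 0
  diff_emp <- mean(r_first[region == "right"]) -
    mean(r_first[region == "left"])
  # direct Monte-Carlo of the stated location-shift model at the region
  # centres (u = +/- 2/3)
  set.seed(1)
  mc_right <- mean(rlaplace(2e5, -6 * (2 / 3), cfg$lag_scale_ms) < 0)
  mc_left <- mean(rlaplace(2e5, -6 * (-2 / 3), cfg$lag_scale_ms) < 0)
  expect_gt(diff_emp, 0)
  expect_gt(mc_right - mc_left, 0)
  expect_equal(diff_emp, mc_right - mc_left, tolerance = 0.12)
})

test_that("degenerate lag configurations are rejected", {
  cfg <- small_cfg(fixdur_log_mean = log(20), fixdur_log_sd = 0.2,
                   lag_scale_ms = 60)
  expect_error(simulate_reading_session(cfg), "degenerate")
  expect_error(sim_config(lag_scale_ms = 0), "lag_scale_ms")
  expect_error(sim_config(lines_per_page = 6), "5 lines")
  expect_error(sim_config(line_length_px = 2000), "fit on the screen")
  expect_error(sim_config(n_participants = 0), "counts")
})

test_that("the count-table shortcut draws Poisson counts around the planted
           means", {
  # all effects zero, intercept log 4: the sample mean is a Poisson mean
  ct <- simulate_count_table(planted_effects = c(left = 0, right = 0),
                             grouping_sds = c(participant = 0, article = 0,
                                              page = 0),
                             n_participants = 20, n_articles = 5,
                             pages_per_article = 5, intercept = log(4),
                             seed = 31)
  n <- nrow(ct)
  expect_lt(abs(mean(ct$count) - 4), 3 * sqrt(4 / n))

  # planted region effects appear as mean ratios
  ct2 <- simulate_count_table(planted_effects = c(left = 0.46,
                                                  right = -0.13),
                              grouping_sds = c(participant = 0, article = 0,
                                               page = 0),
                              n_participants = 40, n_articles = 10,
                              pages_per_article = 5, intercept = log(4),
                              seed = 32)
  ratio <- mean(ct2$count[ct2$region == "left"]) /
    mean(ct2$count[ct2$region == "middle"])
  expect_equal(ratio, exp(0.46), tolerance = 0.05)

  # moment check: participant intercepts have the planted variance
  ct3 <- simulate_count_table(planted_effects = c(left = 0, right = 0),
                              grouping_sds = c(participant = 0.2,
                                               article = 0, page = 0),
                              n_participants = 400, n_articles = 2,
                              pages_per_article = 2, seed = 33)
  b <- attr(ct3, "truth")$ranef$participant
  expect_equal(var(b), 0.04, tolerance = 0.2)
})

test_that("count-table truth round-trips exactly under the same seed", {
  a <- simulate_count_table(seed = 41)
  b <- simulate_count_table(seed = 41)
  expect_identical(a, b)
  expect_identical(attr(a, "truth"), attr(b, "truth"))
  expect_error(simulate_count_table(grouping_sds = c(participant = -1)),
               "SDs")
  expect_error(simulate_count_table(planted_effects = c(left = Inf,
                                                        right = 0)))
})
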