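# Poisson GLM/GLMM fitting, information criteria and likelihood-ratio tests.

toy_counts <- function(counts = c(3, 5, 4),
                       regions = c("left", "middle", "right")) {
  data.frame(
    participant_id = sprintf("P%02d", seq_along(counts) %% 4 + 1),
    group = "test", article_id = "A01",
    page_id = sprintf("pg%02d", seq_along(counts) %% 3 + 1),
    region = rep_len(regions, length(counts)), type = "T6",
    count = counts, stringsAsFactors = FALSE
  )
}

test_that("the design matrix uses treatment coding with middle as reference", {
  rec <- toy_counts(c(2, 3, 4), c("left", "middle", "right"))
  d <- build_design(rec, model_spec())
  expect_equal(colnames(d$X), c("(Intercept)", "regionleft", "regionright"))
  expect_equal(unname(d$X[rec$region == "left", ]), c(1, 1, 0))
  expect_equal(unname(d$X[rec$region == "middle", ]), c(1, 0, 0))
  expect_equal(unname(d$X[rec$region == "right", ]), c(1, 0, 1))
  # permuting records permutes rows identically
  perm <- c(3, 1, 2)
  d2 <- build_design(rec[perm, ], model_spec())
  expect_equal(unname(d2$X), unname(d$X[perm, ]), ignore_attr = TRUE)
  # requesting the region effect without all levels present is an error
  expect_error(build_design(toy_counts(c(1, 2), c("left", "middle")),
                            model_spec()), "right")
  expect_error(build_design(toy_counts(-1, "middle"), model_spec()),
               "non-negative")
})

test_that("intercept-only Poisson GLM recovers log(mean) exactly", {
  fit <- fit_poisson_glm(toy_counts(c(3, 5, 4)),
                         model_spec(region = FALSE, random = character()))
  expect_equal(fit$estimates$estimate, log(4), tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$k, 1L)
})

test_that("constant counts give a flat region model", {
  rec <- toy_counts(rep(7L, 9))
  fit <- fit_poisson_glm(rec, model_spec(random = character()))
  expect_equal(fit$estimates$estimate[fit$estimates$term == "constant"],
               log(7), tolerance = 1e-7)
  expect_equal(fit$estimates$estimate[fit$estimates$term != "constant"],
               c(0, 0), tolerance = 1e-7)
})

test_that("GLM log-likelihood and score match a direct evaluation", {
  set.seed(8)
  for (rep in 1:5) {
    rec <- toy_counts(rpois(30, 5),
                      sample(c("left", "middle", "right"), 30, TRUE,
                             prob = c(.4, .3, .3)))
    if (length(unique(rec$region)) < 3) next
    fit <- fit_poisson_glm(rec, model_spec(random = character()))
    d <- build_design(rec, model_spec(random = character()))
    beta <- fit$estimates$estimate
    eta <- drop(d$X %*% beta)
    ll <- sum(d$y * eta - exp(eta) - lfactorial(d$y))
    expect_equal(fit$loglik, ll, tolerance = 1e-8)
    grad <- drop(t(d$X) %*% (d$y - exp(eta)))
    expect_lt(max(abs(grad)), 1e-4)
    # Wald identity
    expect_equal(fit$estimates$z,
                 fit$estimates$estimate / fit$estimates$se)
    # information-criterion identities
    expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$k)
    expect_equal(fit$bic, -2 * fit$loglik + fit$k * log(fit$n_obs))
  }
})

test_that("GLMM with zero planted heterogeneity collapses to the GLM", {
  # counts and cells-per-group chosen large enough that boundary-adjacent
  # variance estimates perturb the fixed effects by less than the tolerance
  ct <- simulate_count_table(
    planted_effects = c(left = 0.4, right = -0.1),
    grouping_sds = c(participant = 0, article = 0, page = 0),
    n_participants = 36, n_articles = 7, pages_per_article = 5,
    intercept = log(50), seed = 301)
  glm_fit <- fit_poisson_glm(ct, model_spec(random = character()))
  glmm_fit <- fit_poisson_glmm(ct, control = fast_glmm_control())
  expect_lt(max(abs(glmm_fit$estimates$estimate -
                      glm_fit$estimates$estimate)), 1e-4)
  expect_true(all(glmm_fit$random$variance < 1e-4))
  expect_equal(glmm_fit$k, 6L) # 3 fixed + 3 variance components
})

test_that("GLMM recovers planted fixed effects and variance components", {
  ct <- simulate_count_table(n_participants = 36, n_articles = 7,
                             pages_per_article = 5, seed = 52)
  fit <- fit_poisson_glmm(ct, control = fast_glmm_control())
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  se <- setNames(fit$estimates$se, fit$estimates$term)
  expect_lt(abs(est["left"] - 0.46), 3 * se["left"])
  expect_lt(abs(est["right"] + 0.13), 3 * se["right"])
  pr <- fit$random[fit$random$factor == "participant", ]
  expect_equal(pr$n_groups, 36L)
  expect_gt(pr$sd, 0.1)
  expect_lt(pr$sd, 0.45)
  expect_equal(fit$random$sd, sqrt(fit$random$variance))
})

test_that("the Laplace marginal log-likelihood matches adaptive quadrature
           on a small one-factor model", {
  set.seed(6)
  # a strongly separated pair of participants keeps the variance estimate
  # off the boundary, so the quadrature oracle is well defined
  ct <- simulate_count_table(
    planted_effects = c(left = 0.3, right = -0.2),
    grouping_sds = c(participant = 1, article = 0, page = 0),
    n_participants = 2, n_articles = 2, pages_per_article = 2,
    intercept = log(6), seed = 62)
  fit <- fit_poisson_glmm(ct, model_spec(random = "participant"))
  # oracle: numerically integrate the Poisson likelihood over the random
  # intercept per participant at the fitted parameters
  beta <- setNames(fit$estimates$estimate, fit$estimates$term)
  sigma <- fit$random$sd[1]
  eta0 <- beta["constant"] +
    ifelse(ct$region == "left", beta["left"],
           ifelse(ct$region == "right", beta["right"], 0))
  expect_gt(sigma, 1e-4) # the oracle needs a non-degenerate variance
  ll_quad <- 0
  for (pid in unique(ct$participant_id)) {
    idx <- ct$participant_id == pid
    log_f <- function(ui) {
      sum(dpois(ct$count[idx], exp(eta0[idx] + ui), log = TRUE)) +
        dnorm(ui, 0, sigma, log = TRUE)
    }
    scale <- log_f(0) # rescale to keep the integrand in floating range
    f <- function(u) vapply(u, function(ui) exp(log_f(ui) - scale),
                            numeric(1))
    ll_quad <- ll_quad + scale +
      log(integrate(f, -Inf, Inf, rel.tol = 1e-10)$value)
  }
  expect_equal(fit$loglik, ll_quad, tolerance = 1e-3)
})

test_that("singular grouping factors are dropped with a warning", {
  ct <- simulate_count_table(n_participants = 6, n_articles = 1,
                             pages_per_article = 3, seed = 62)
  expect_warning(
    fit <- fit_poisson_glmm(ct, model_spec(random = c("participant",
                                                      "article")),
                            control = fast_glmm_control()),
    "singular grouping")
  expect_equal(fit$random$factor, "participant")
  ct1 <- ct[ct$participant_id == "P01", ]
  expect_warning(glm_back <- fit_poisson_glmm(
    ct1, model_spec(random = "participant")), "singular")
  expect_null(glm_back$random)
  expect_match(glm_back$note, "GLM")
})

test_that("nested fits compare by likelihood ratio as expected", {
  ct <- simulate_count_table(n_participants = 12, n_articles = 3,
                             pages_per_article = 3, seed = 63)
  null_fit <- fit_poisson_glmm(ct, model_spec(region = FALSE),
                               control = fast_glmm_control())
  full_fit <- fit_poisson_glmm(ct, model_spec(region = TRUE),
                               control = fast_glmm_control())
  # richer nested model fits at least as well
  expect_gte(full_fit$loglik, null_fit$loglik - 1e-6)
  lrt <- lrt_compare(null_fit, full_fit)
  expect_equal(lrt$df, 2L)
  expect_equal(lrt$chisq, 2 * (full_fit$loglik - null_fit$loglik))
  expect_equal(lrt$p, pchisq(lrt$chisq, 2, lower.tail = FALSE))

  same <- lrt_compare(full_fit, full_fit)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)
  expect_error(lrt_compare(full_fit, null_fit), "not nested")
})

test_that("report tables mirror the two-column layout and flag boundary
           fits", {
  ct <- simulate_count_table(
    grouping_sds = c(participant = 0, article = 0, page = 0),
    n_participants = 10, n_articles = 2, pages_per_article = 2, seed = 64)
  null_fit <- fit_poisson_glmm(ct, model_spec(region = FALSE),
                               control = fast_glmm_control())
  full_fit <- fit_poisson_glmm(ct, model_spec(region = TRUE),
                               control = fast_glmm_control())
  tab <- format_table(null_fit, full_fit, label = "T6")
  expect_s3_class(tab, "binoc_fit_table")
  expect_true(all(c("Observations", "Log likelihood", "Akaike inf. crit.",
                    "Bayesian inf. crit.") %in% tab$rows$quantity))
  expect_true(any(grepl("left", tab$rows$quantity)))
  txt <- capture.output(print(tab))
  expect_true(any(grepl("sides of screen", txt)))
  if (all(full_fit$random$variance == 0)) {
    expect_match(tab$note, "equal to zero")
  }
  # JSON round-trip of the table
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(tab, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$n_obs, tab$n_obs)
  expect_equal(back$region$loglik, tab$region$loglik, tolerance = 1e-12)
})
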