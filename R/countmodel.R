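# Poisson count models for fixation-pair counts by screen region:
# plain GLM, random-intercept GLMM (participant / article / page), nested
# model comparison by likelihood ratio, and paper-style report tables.

.RANDOM_FACTORS <- c("participant", "article", "page")

#' Specify a Poisson count model
#'
#' Fixed effects are the intercept and, optionally, treatment-coded screen
#' region with `middle` as the reference level (so `left` and `right`
#' coefficients are log rate ratios versus the middle of the screen). Random
#' intercepts may be requested for `participant`, `article` and `page`;
#' "page" is keyed by (article, page order within article).
#'
#' @param region Include the region fixed effect? Default `TRUE`.
#' @param random Character subset of `c("participant", "article", "page")`;
#'   empty for a plain GLM.
#' @return An object of class `binoc_model_spec`.
#' @export
model_spec <- function(region = TRUE,
                       random = c("participant", "article", "page")) {
  random <- as.character(random)
  if (!all(random %in% .RANDOM_FACTORS)) {
    stop("random factors must be among: ",
         paste(.RANDOM_FACTORS, collapse = ", "))
  }
  structure(list(region = isTRUE(region), random = random,
                 family = "poisson"),
            class = "binoc_model_spec")
}

#' Build the model frame for a count-model specification
#'
#' Returns the response, the fixed-effect design matrix with treatment
#' coding (stable column order: intercept, left, right) and the grouping
#' factors. The page grouping factor is the interaction of article and page
#' order, so "page 1" of different articles are distinct levels.
#'
#' @param records A count-record data frame (see [count_table()]).
#' @param spec A [model_spec()].
#' @return A list with `y`, `X`, `groups` (named list of factors) and the
#'   model `data` frame used downstream.
#' @export
build_design <- function(records, spec = model_spec()) {
  stopifnot(inherits(spec, "binoc_model_spec"), is.data.frame(records))
  if (nrow(records) == 0L) stop("no count records")
  if (any(records$count < 0) || any(records$count != round(records$count))) {
    stop("counts must be non-negative integers")
  }
  region <- factor(as.character(records$region),
                   levels = c("middle", "left", "right"))
  if (anyNA(region)) stop("invalid region labels present")
  if (spec$region) {
    missing_lev <- setdiff(c("middle", "left", "right"),
                           unique(as.character(region)))
    if (length(missing_lev)) {
      stop("region level(s) absent from the data: ",
           paste(missing_lev, collapse = ", "))
    }
  }
  data <- data.frame(
    count = as.integer(records$count),
    region = region,
    participant = factor(records$participant_id),
    article = factor(records$article_id),
    page = factor(paste(records$article_id, records$page_id, sep = ":"))
  )
  X <- if (spec$region) {
    model.matrix(~region, data = data)
  } else {
    model.matrix(~1, data = data)
  }
  list(y = data$count, X = X,
       groups = lapply(setNames(spec$random, spec$random),
                       function(f) data[[f]]),
       data = data)
}

.term_names <- function(cols) {
  map <- c("(Intercept)" = "constant", "regionleft" = "left",
           "regionright" = "right")
  unname(map[cols])
}

.fit_result <- function(estimates, random, loglik, n_obs, converged, spec,
                        engine) {
  k <- nrow(estimates) + if (is.null(random)) 0L else nrow(random)
  res <- structure(
    list(estimates = estimates, random = random, loglik = loglik, k = k,
         aic = -2 * loglik + 2 * k, bic = -2 * loglik + k * log(n_obs),
         n_obs = n_obs, converged = converged, spec = spec, engine = engine),
    class = "binoc_fit"
  )
  stopifnot(isTRUE(all.equal(res$aic, -2 * res$loglik + 2 * res$k)),
            isTRUE(all.equal(res$bic,
                             -2 * res$loglik + res$k * log(res$n_obs))))
  res
}

#' Fit a Poisson GLM to count records
#'
#' Maximum-likelihood Poisson regression (log link) of cell counts on screen
#' region, via iteratively reweighted least squares. Wald standard errors
#' come from the observed information; AIC/BIC use
#' `k = number of fixed coefficients`.
#'
#' @inheritParams build_design
#' @return An object of class `binoc_fit` with elements `estimates` (term,
#'   estimate, se, z, p), `random` (`NULL` here), `loglik`, `k`, `aic`,
#'   `bic`, `n_obs` and `converged`.
#' @export
fit_poisson_glm <- function(records, spec = model_spec(random = character())) {
  d <- build_design(records, spec)
  form <- if (spec$region) count ~ region else count ~ 1
  fit <- stats::glm(form, family = stats::poisson(), data = d$data)
  est <- summary(fit)$coefficients
  estimates <- data.frame(
    term = .term_names(rownames(est)),
    estimate = est[, 1], se = est[, 2], z = est[, 3], p = est[, 4],
    row.names = NULL
  )
  .fit_result(estimates, NULL, as.numeric(logLik(fit)), nrow(d$data),
              fit$converged, spec, "glm")
}

#' Fit a Poisson GLMM with crossed random intercepts
#'
#' Laplace-approximated maximum likelihood for a Poisson mixed model with
#' region as fixed effect and independent random intercepts for any subset of
#' participant, article and page (crossed factors). Variance components may
#' sit on the zero boundary; they are reported as 0 with a note rather than
#' an error. `k` counts fixed coefficients plus variance components, so the
#' usual AIC/BIC identities hold. Random factors with fewer than two levels
#' are dropped with a warning; with no random factors left the model reduces
#' to [fit_poisson_glm()].
#'
#' @inheritParams build_design
#' @param control A [lme4::glmerControl()] passed to the optimizer;
#'   `lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE)` is a
#'   substantially faster setting that leaves estimates, standard errors and
#'   log-likelihoods essentially unchanged on these models.
#' @return An object of class `binoc_fit`; `random` is a data frame with one
#'   row per variance component (`factor`, `variance`, `sd`, `n_groups`).
#' @export
fit_poisson_glmm <- function(records, spec = model_spec(),
                             control = lme4::glmerControl()) {
  stopifnot(inherits(spec, "binoc_model_spec"))
  d <- build_design(records, spec)
  keep <- vapply(d$groups, function(f) nlevels(droplevels(f)) >= 2,
                 logical(1))
  if (any(!keep)) {
    warning("dropping singular grouping factor(s): ",
            paste(names(keep)[!keep], collapse = ", "))
    spec <- model_spec(region = spec$region, random = spec$random[keep])
  }
  if (length(spec$random) == 0L) {
    res <- fit_poisson_glm(records,
                           model_spec(region = spec$region,
                                      random = character()))
    res$note <- "no usable random factors; plain GLM fitted"
    return(res)
  }
  fixed <- if (spec$region) "count ~ region" else "count ~ 1"
  form <- stats::as.formula(
    paste(fixed, paste(sprintf("(1 | %s)", spec$random), collapse = " + "),
          sep = " + "))
  conv <- TRUE
  fit <- withCallingHandlers(
    lme4::glmer(form, family = stats::poisson(), data = d$data,
                control = control),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        conv <<- FALSE
      }
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      # boundary (singular) fits are reported via the zero-variance note
      if (grepl("singular", conditionMessage(m), ignore.case = TRUE)) {
        invokeRestart("muffleMessage")
      }
    }
  )
  est <- coef(summary(fit))
  estimates <- data.frame(
    term = .term_names(rownames(est)),
    estimate = est[, 1], se = est[, 2], z = est[, 3], p = est[, 4],
    row.names = NULL
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  vc <- vc[match(spec$random, vc$grp), , drop = FALSE]
  ng <- lme4::ngrps(fit)
  random <- data.frame(
    factor = spec$random,
    variance = ifelse(vc$vcov < 1e-10, 0, vc$vcov),
    sd = ifelse(vc$vcov < 1e-10, 0, vc$sdcor),
    n_groups = as.integer(ng[spec$random]),
    row.names = NULL
  )
  ll <- as.numeric(logLik(fit))
  res <- .fit_result(estimates, random, ll, nrow(d$data), conv, spec,
                     "glmer")
  stopifnot(res$k == attr(logLik(fit), "df"))
  if (any(random$variance == 0)) {
    res$note <- "random intercept variance(s) at the zero boundary"
  }
  res
}

#' @export
print.binoc_fit <- function(x, digits = 3, ...) {
  cat("Poisson ", if (is.null(x$random)) "GLM" else "GLMM (Laplace ML)",
      ": count ~ ",
      if (x$spec$region) "region (middle as reference)" else "1", "\n",
      sep = "")
  est <- x$estimates
  est$estimate <- round(est$estimate, digits)
  est$se <- round(est$se, digits)
  est$z <- round(est$z, 2)
  est$p <- signif(est$p, 2)
  print(est, row.names = FALSE)
  if (!is.null(x$random)) {
    cat("random intercepts:\n")
    r <- x$random
    r$variance <- round(r$variance, 4)
    r$sd <- round(r$sd, 4)
    print(r, row.names = FALSE)
  }
  cat(sprintf("n = %d, logLik = %.3f, k = %d, AIC = %.3f, BIC = %.3f\n",
              x$n_obs, x$loglik, x$k, x$aic, x$bic))
  if (!x$converged) cat("WARNING: fit did not converge cleanly\n")
  if (!is.null(x$note)) cat("note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Information criteria from a log-likelihood
#'
#' `AIC = -2 l + 2 k` and `BIC = -2 l + k log(n)`, with `k` the number of
#' estimated parameters (fixed coefficients plus variance components) and
#' `n` the number of observations — the same arithmetic applied to every fit
#' result in this package.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n_obs Number of observations (needed for BIC only).
#' @return A list with `aic` and `bic` (the latter `NA` without `n_obs`).
#' @export
#' @examples
#' information_criteria(-8252.810, k = 4, n_obs = 6168)
information_criteria <- function(loglik, k, n_obs = NULL) {
  list(aic = -2 * loglik + 2 * k,
       bic = if (is.null(n_obs)) NA_real_ else -2 * loglik + k * log(n_obs))
}

#' Likelihood-ratio test between nested count models
#'
#' `chisq = 2 (l_full - l_null)` on `df = k_full - k_null` degrees of
#' freedom, with an upper-tail chi-square p-value — the standard `anova`-style
#' comparison of a null model against the model adding the region predictor.
#'
#' @param null_fit,full_fit `binoc_fit` objects on the same data, with the
#'   null model's terms a subset of the full model's.
#' @return An object of class `binoc_lrt`: list with `chisq`, `df`, `p`.
#' @export
lrt_compare <- function(null_fit, full_fit) {
  stopifnot(inherits(null_fit, "binoc_fit"), inherits(full_fit, "binoc_fit"))
  if (null_fit$n_obs != full_fit$n_obs) {
    stop("models were fitted to different numbers of observations")
  }
  nested <- all(null_fit$estimates$term %in% full_fit$estimates$term) &&
    full_fit$k >= null_fit$k &&
    all(if (is.null(null_fit$random)) character() else
      null_fit$random$factor %in%
        (if (is.null(full_fit$random)) character() else
           full_fit$random$factor))
  if (!nested) stop("models are not nested")
  chisq <- 2 * (full_fit$loglik - null_fit$loglik)
  if (chisq < 0 && chisq > -1e-6) chisq <- 0
  df <- full_fit$k - null_fit$k
  p <- if (df == 0) as.numeric(chisq <= 0) else
    pchisq(chisq, df, lower.tail = FALSE)
  structure(list(chisq = chisq, df = df, p = p), class = "binoc_lrt")
}

#' @export
print.binoc_lrt <- function(x, ...) {
  cat(sprintf("LRT: chisq = %.3f, df = %d, p = %.4g\n", x$chisq, x$df, x$p))
  invisible(x)
}

#' Two-column null-vs-region report table
#'
#' Formats a null fit and a region fit side by side in the conventional
#' mixed-model report layout: fixed-effect estimates with p-values in
#' brackets, a random-effects variance/SD block, then observations,
#' log-likelihood, AIC and BIC at three decimals. A footnote flags variance
#' components estimated at zero.
#'
#' @param null_fit,full_fit `binoc_fit` objects on the same data.
#' @param label Optional heading (e.g. the type being modelled).
#' @return An object of class `binoc_fit_table`: list with `label`, `rows`
#'   (a data frame of formatted cells), `note`, and the two fits' summary
#'   numbers; its print method renders the table as text.
#' @export
format_table <- function(null_fit, full_fit, label = "") {
  stopifnot(inherits(null_fit, "binoc_fit"), inherits(full_fit, "binoc_fit"),
            null_fit$n_obs == full_fit$n_obs)
  fmt_est <- function(fit, term) {
    i <- match(term, fit$estimates$term)
    if (is.na(i)) return("")
    p <- fit$estimates$p[i]
    sprintf("%.3f (%s)", fit$estimates$estimate[i],
            if (p < 0.001) "<.001" else sub("^0", "", sprintf("%.3f", p)))
  }
  terms <- unique(c(full_fit$estimates$term, null_fit$estimates$term))
  terms <- c(setdiff(terms, "constant"), "constant")
  rows <- data.frame(
    quantity = terms,
    null = vapply(terms, function(t) fmt_est(null_fit, t), ""),
    region = vapply(terms, function(t) fmt_est(full_fit, t), ""),
    stringsAsFactors = FALSE
  )
  rand <- full_fit$random
  if (!is.null(rand)) {
    for (i in seq_len(nrow(rand))) {
      rows <- rbind(rows, data.frame(
        quantity = sprintf("%s (%d) variance/SD", rand$factor[i],
                           rand$n_groups[i]),
        null = "",
        region = sprintf("%.4f / %.4f", rand$variance[i], rand$sd[i]),
        stringsAsFactors = FALSE
      ))
    }
  }
  fmt_n <- function(v) format(v, big.mark = ",", trim = TRUE)
  rows <- rbind(rows, data.frame(
    quantity = c("Observations", "Log likelihood", "Akaike inf. crit.",
                 "Bayesian inf. crit."),
    null = c(fmt_n(null_fit$n_obs), sprintf("%.3f", null_fit$loglik),
             sprintf("%.3f", null_fit$aic), sprintf("%.3f", null_fit$bic)),
    region = c(fmt_n(full_fit$n_obs), sprintf("%.3f", full_fit$loglik),
               sprintf("%.3f", full_fit$aic), sprintf("%.3f", full_fit$bic)),
    stringsAsFactors = FALSE
  ))
  note <- NULL
  if (!is.null(rand) && nrow(rand) && all(rand$variance == 0)) {
    note <- "All random intercepts were equal to zero."
  } else if (!is.null(rand) && any(rand$variance == 0)) {
    note <- paste("Random intercepts equal to zero:",
                  paste(rand$factor[rand$variance == 0], collapse = ", "))
  }
  structure(list(label = label, rows = rows, note = note,
                 null = list(loglik = null_fit$loglik, k = null_fit$k,
                             aic = null_fit$aic, bic = null_fit$bic),
                 region = list(loglik = full_fit$loglik, k = full_fit$k,
                               aic = full_fit$aic, bic = full_fit$bic),
                 n_obs = full_fit$n_obs),
            class = "binoc_fit_table")
}

#' @export
print.binoc_fit_table <- function(x, ...) {
  if (nzchar(x$label)) cat(x$label, "\n")
  cat(sprintf("%-32s %-18s %-18s\n", "", "null model", "sides of screen"))
  cat(sprintf("%-32s %-18s %-18s\n", "", "(1)", "(2)"))
  for (i in seq_len(nrow(x$rows))) {
    cat(sprintf("%-32s %-18s %-18s\n", x$rows$quantity[i], x$rows$null[i],
                x$rows$region[i]))
  }
  if (!is.null(x$note)) cat("Note. ", x$note, "\n", sep = "")
  invisible(x)
}
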