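#' Build the segmented-regression design from a share panel
#'
#' Codes each practice-month for interrupted time series analysis around a
#' safety communication issued in `dhpc_month`:
#'
#' * `t` — months since the anchor month (the month *before* the
#'   communication), so the intercept is the level of prescribing just before
#'   the warning;
#' * `post` — 1 from the month *after* the communication (`t >= 2`);
#' * `s = (t - 2) * post` — months elapsed since the first post period, so
#'   the `post` coefficient is the immediate level change and the `s`
#'   coefficient the change in monthly trend;
#' * `month` — calendar-month factor (January reference) for seasonality.
#'
#' The communication month itself (`t = 1`) is a transition month: the letter
#' arrives during it, so it belongs cleanly to neither segment and is excluded
#' by default. Rows with an undefined share (no class prescribing) are
#' dropped; the count is attached as attribute `n_dropped_share`.
#'
#' @param share_panel a share panel from [compute_share()].
#' @param dhpc_month `YYYYMM` month of the safety communication.
#' @param include_transition keep the communication month as a pre-period row
#'   (`t = 1`, `post = 0`) instead of excluding it.
#' @return a design tibble with columns `practice_id`, `period`, `t`, `post`,
#'   `s`, `month`, `share_pct`, and attributes `dhpc_month`, `anchor_period`.
#' @export
build_design <- function(share_panel, dhpc_month, include_transition = FALSE) {
  d <- month_index(dhpc_month)
  pr <- range(month_index(share_panel$period))
  if (d - pr[1] < 2 || pr[2] - d < 2) {
    stop("panel must span at least 2 months on each side of `dhpc_month`",
         call. = FALSE)
  }
  out <- share_panel |>
    dplyr::mutate(
      t = month_index(.data$period) - d + 1L,
      post = as.integer(.data$t >= 2L),
      s = (.data$t - 2L) * .data$post,
      month = factor(month.abb[month_of_year(.data$period)], levels = month.abb)
    )
  n_undef <- sum(is.na(out$share_pct))
  out <- dplyr::filter(out, !is.na(.data$share_pct))
  if (!include_transition) out <- dplyr::filter(out, .data$t != 1L)
  out <- out |>
    dplyr::select("practice_id", "period", "t", "post", "s", "month",
                  "share_pct") |>
    dplyr::arrange(.data$practice_id, .data$t)
  attr(out, "dhpc_month") <- as.integer(dhpc_month)
  attr(out, "anchor_period") <- index_to_period(d - 1L)
  attr(out, "n_dropped_share") <- n_undef
  out
}

# map between user-facing random-effect names and design columns
re_terms <- c(intercept = "(Intercept)", slope = "t",
              level_change = "post", slope_change = "s")

model_formula <- function(seasonality) {
  if (seasonality) share_pct ~ t + post + s + month else share_pct ~ t + post + s
}

#' Fit the multilevel segmented regression
#'
#' Maximises the (restricted) likelihood of the linear mixed model
#' \deqn{y_{pt} = X_{pt}\beta + Z_{pt} b_p + \varepsilon_{pt}, \quad
#'   b_p \sim N(0, G)}
#' where the fixed part contains the four structural terms of the segmented
#' design (level, trend, level change, trend change) plus optional
#' calendar-month effects, `G` is an unstructured covariance over the
#' requested practice random effects, and the within-practice errors are
#' independent (`ar_order = 0`) or follow a stationary AR(2) correlation
#' (`ar_order = 2`). Estimation is delegated to `lme4::lmer` (no residual
#' correlation) or `nlme::lme` (AR errors); practice-level BLUPs and their
#' conditional standard errors are then computed from the estimated
#' parameters (see [classify_practices()]).
#'
#' On failure the fit falls back along a documented ladder — drop the AR
#' terms, then drop the slope-change random effect — recording each step in
#' `$fallback`; with `strict = TRUE` any fallback or convergence warning is
#' an error instead.
#'
#' @param design a design tibble from [build_design()].
#' @param random_spec subset of `c("intercept", "slope", "level_change",
#'   "slope_change")`: which parameters vary by practice. Empty for a purely
#'   fixed-effects (OLS) fit.
#' @param ar_order 0 (independent errors) or 2 (stationary AR(2) residual
#'   correlation within practice; consecutive design rows are treated as
#'   consecutive months).
#' @param seasonality include calendar-month fixed effects (January
#'   reference).
#' @param method `"REML"` (default) or `"ML"`; likelihood-ratio comparisons
#'   of random-effect structures should use `"ML"` fits.
#' @param strict error on non-convergence instead of flagging.
#' @return an object of class `its_fit`: a list with the coefficient table
#'   (`coefficients`: term, estimate, SE, Wald 95% CI, p), the four
#'   structural estimates (`beta`), `G`, `rho`, `sigma2`, `logLik`,
#'   `blups` (per-practice estimates with conditional SEs), fitted values
#'   and marginal residuals, and bookkeeping fields (`engine`, `method`,
#'   `converged`, `fallback`, `messages`).
#' @export
fit_segmented <- function(design,
                          random_spec = c("intercept", "slope",
                                          "level_change", "slope_change"),
                          ar_order = 2, seasonality = TRUE,
                          method = c("REML", "ML"), strict = FALSE) {
  method <- match.arg(method)
  stopifnot(all(random_spec %in% names(re_terms)), ar_order %in% c(0, 1, 2))
  # canonical order: intercept, slope, level_change, slope_change
  random_spec <- names(re_terms)[names(re_terms) %in% random_spec]
  design <- dplyr::arrange(design, .data$practice_id, .data$t)
  n_practices <- dplyr::n_distinct(design$practice_id)
  if (length(random_spec) > 0 && n_practices < 2) {
    stop("random effects need at least 2 practices", call. = FALSE)
  }

  attempt <- try_fit(design, random_spec, ar_order, seasonality, method)
  fallback <- character(0)
  if (inherits(attempt, "try-error") && ar_order > 0) {
    fallback <- c(fallback, "dropped AR correlation")
    ar_order <- 0
    attempt <- try_fit(design, random_spec, ar_order, seasonality, method)
  }
  if (inherits(attempt, "try-error") && "slope_change" %in% random_spec) {
    fallback <- c(fallback, "dropped slope-change random effect")
    random_spec <- setdiff(random_spec, "slope_change")
    attempt <- try_fit(design, random_spec, ar_order, seasonality, method)
  }
  if (inherits(attempt, "try-error")) {
    stop("segmented model failed to fit: ", attr(attempt, "condition")$message,
         call. = FALSE)
  }
  if (strict && (length(fallback) > 0 || !attempt$converged)) {
    stop("segmented model did not converge cleanly: ",
         paste(c(fallback, attempt$messages), collapse = "; "), call. = FALSE)
  }

  fit <- attempt
  fit$fallback <- fallback
  fit$random_spec <- random_spec
  fit$ar_order <- ar_order
  fit$seasonality <- seasonality
  fit$method <- method
  fit$n_obs <- nrow(design)
  fit$n_practices <- n_practices

  # BLUPs with conditional SEs from the estimated variance components
  if (length(random_spec) > 0) {
    fit$blups <- compute_blups(design, fit, seasonality)
  } else {
    fit$blups <- NULL
  }
  fit$residuals <- design$share_pct - fit$fitted
  class(fit) <- "its_fit"
  fit
}

try_fit <- function(design, random_spec, ar_order, seasonality, method) {
  try(fit_engine(design, random_spec, ar_order, seasonality, method),
      silent = TRUE)
}

fit_engine <- function(design, random_spec, ar_order, seasonality, method) {
  fml <- model_formula(seasonality)
  msgs <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr,
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      })
  }
  re_cols <- unname(re_terms[random_spec])
  re_rhs <- paste(c(if ("intercept" %in% random_spec) "1" else "0",
                    setdiff(re_cols, "(Intercept)")), collapse = " + ")

  if (length(random_spec) == 0 && ar_order == 0) {
    m <- stats::lm(fml, data = design)
    est <- stats::coef(m)
    se <- sqrt(diag(stats::vcov(m)))
    ll <- as.numeric(stats::logLik(m))
    G <- matrix(0, 0, 0); rho <- numeric(0); sigma2 <- stats::sigma(m)^2
    fitted <- as.numeric(stats::fitted(m))
    engine <- "lm"
    converged <- TRUE
  } else if (ar_order == 0) {
    f2 <- stats::as.formula(paste(deparse(fml[[2]]), "~",
                                  paste(deparse(fml[[3]]), collapse = ""),
                                  "+ (", re_rhs, "| practice_id)"))
    fit_one <- function(optimizer) {
      collect(lme4::lmer(f2, data = design, REML = method == "REML",
                         control = lme4::lmerControl(optimizer = optimizer)))
    }
    # the default optimizer occasionally stalls in a degenerate local optimum
    # for unstructured G; restart from bobyqa and keep the better likelihood
    m <- fit_one("nloptwrap")
    if (lme4::isSingular(m) || !isTRUE(m@optinfo$conv$opt == 0)) {
      m2 <- fit_one("bobyqa")
      if (as.numeric(stats::logLik(m2)) > as.numeric(stats::logLik(m))) m <- m2
    }
    est <- lme4::fixef(m)
    se <- sqrt(diag(as.matrix(stats::vcov(m))))
    ll <- as.numeric(stats::logLik(m))
    G <- as.matrix(lme4::VarCorr(m)$practice_id)
    attr(G, "stddev") <- attr(G, "correlation") <- NULL
    rho <- numeric(0)
    sigma2 <- stats::sigma(m)^2
    fitted <- as.numeric(stats::model.matrix(m) %*% est)
    engine <- "lmer"
    # the optimizer's own return code; lme4's post-hoc gradient checks are
    # recorded in `messages` but are known to flag healthy large-n fits
    converged <- isTRUE(m@optinfo$conv$opt == 0)
  } else {
    ref <- stats::as.formula(paste("~", re_rhs, "| practice_id"))
    m <- collect(nlme::lme(
      fixed = fml, random = ref, data = design,
      correlation = nlme::corARMA(p = ar_order, q = 0, form = ~ 1 | practice_id),
      method = method,
      control = nlme::lmeControl(maxIter = 200, msMaxIter = 500,
                                 msMaxEval = 2000, niterEM = 100,
                                 returnObject = FALSE)
    ))
    est <- nlme::fixef(m)
    se <- sqrt(diag(as.matrix(stats::vcov(m))))
    ll <- as.numeric(stats::logLik(m))
    G <- unname(as.matrix(nlme::getVarCov(m)))
    dimnames(G) <- NULL
    rho <- as.numeric(stats::coef(m$modelStruct$corStruct, unconstrained = FALSE))
    sigma2 <- m$sigma^2
    X <- stats::model.matrix(fml, data = design)
    fitted <- as.numeric(X %*% est[colnames(X)])
    engine <- "lme"
    converged <- TRUE  # lmeControl(returnObject = FALSE) errors otherwise
  }

  G <- as.matrix(G)
  if (length(random_spec) > 0) dimnames(G) <- list(random_spec, random_spec)
  z <- stats::qnorm(0.975)
  coefficients <- tibble::tibble(
    term = names(est), estimate = unname(est), se = unname(se),
    ci_low = unname(est - z * se), ci_high = unname(est + z * se),
    p = 2 * stats::pnorm(-abs(unname(est) / unname(se)))
  )
  structural <- c(level = "(Intercept)", slope = "t",
                  level_change = "post", slope_change = "s")
  beta <- stats::setNames(est[structural], names(structural))
  list(coefficients = coefficients, beta = beta, G = G, rho = rho,
       sigma2 = sigma2, logLik = ll, fitted = fitted, engine = engine,
       messages = msgs, converged = converged)
}

# stationary AR(2) correlation matrix for consecutive positions 1..n
ar_corr_matrix <- function(n, rho) {
  if (length(rho) == 0 || all(rho == 0)) return(diag(n))
  acf <- numeric(n)
  acf[1] <- 1
  if (length(rho) == 1) {
    for (k in 2:n) acf[k] <- rho[1] * acf[k - 1]
  } else {
    acf[2] <- rho[1] / (1 - rho[2])
    if (n > 2) for (k in 3:n) acf[k] <- rho[1] * acf[k - 1] + rho[2] * acf[k - 2]
  }
  stats::toeplitz(acf)
}

# per-practice BLUPs b_hat = G Z' V^{-1} (y - X beta_hat) and conditional
# variances G - G Z' V^{-1} Z G, with V = Z G Z' + sigma2 * R
compute_blups <- function(design, fit, seasonality) {
  X <- stats::model.matrix(model_formula(seasonality), data = design)
  beta_full <- fit$coefficients$estimate
  names(beta_full) <- fit$coefficients$term
  resid_marg <- design$share_pct - as.numeric(X %*% beta_full[colnames(X)])
  re_cols <- unname(re_terms[fit$random_spec])
  Zall <- X[, re_cols, drop = FALSE]
  G <- fit$G
  q <- ncol(G)
  split_idx <- split(seq_len(nrow(design)), design$practice_id)
  out_b <- matrix(NA_real_, length(split_idx), q)
  out_se <- matrix(NA_real_, length(split_idx), q)
  for (i in seq_along(split_idx)) {
    idx <- split_idx[[i]]
    Z <- Zall[idx, , drop = FALSE]
    R <- ar_corr_matrix(length(idx), fit$rho)
    V <- Z %*% G %*% t(Z) + fit$sigma2 * R
    GZt_Vinv <- G %*% t(Z) %*% solve(V)
    out_b[i, ] <- GZt_Vinv %*% resid_marg[idx]
    cv <- G - GZt_Vinv %*% Z %*% G
    out_se[i, ] <- sqrt(pmax(diag(cv), 0))
  }
  colnames(out_b) <- paste0("b_", fit$random_spec)
  colnames(out_se) <- paste0("se_", fit$random_spec)
  dplyr::bind_cols(tibble::tibble(practice_id = names(split_idx)),
                   tibble::as_tibble(out_b), tibble::as_tibble(out_se))
}

#' @exportS3Method base::print
print.its_fit <- function(x, ...) {
  cat("Multilevel segmented regression (engine:", x$engine,
      "| method:", x$method, ")\n")
  cat(x$n_obs, "practice-months,", x$n_practices, "practices\n")
  if (length(x$fallback)) cat("fallback:", paste(x$fallback, collapse = "; "), "\n")
  structural <- c("(Intercept)", "t", "post", "s")
  print(as.data.frame(dplyr::filter(x$coefficients, .data$term %in% structural)),
        digits = 4, row.names = FALSE)
  if (length(x$rho)) cat("AR coefficients:", paste(round(x$rho, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Human-readable fit summary table
#'
#' Relabels the structural coefficients of an `its_fit` in the conventional
#' interrupted-time-series wording (level at the anchor month, monthly trend,
#' change in level, change in trend), followed by any calendar-month effects.
#'
#' @param fit an `its_fit`.
#' @return a tibble: parameter, estimate, 95% CI bounds, p.
#' @export
fit_summary_table <- function(fit) {
  labels <- c("(Intercept)" = "Level at anchor month (intercept)",
              t = "Monthly trend (slope)",
              post = "Change in level immediately post warning",
              s = "Change in monthly trend post warning")
  fit$coefficients |>
    dplyr::mutate(parameter = dplyr::coalesce(labels[.data$term], .data$term),
                  .before = 1) |>
    dplyr::select("parameter", "estimate", "ci_low", "ci_high", "p")
}

#' Likelihood-ratio test between nested random-effect structures
#'
#' Compares two [fit_segmented()] fits of the same data and fixed effects
#' whose random-effect sets are nested. The statistic is twice the
#' log-likelihood difference; the reference distribution is a chi-square on
#' the difference in variance-covariance parameter count (unstructured
#' `q(q+1)/2` plus any AR coefficients). This is conservative for variance
#' parameters on the boundary; both fits should use `method = "ML"`.
#'
#' @param fit_full,fit_reduced `its_fit` objects, reduced nested in full.
#' @return a list: `statistic`, `df`, `p_value`.
#' @export
lr_test_random_effect <- function(fit_full, fit_reduced) {
  if (!all(fit_reduced$random_spec %in% fit_full$random_spec) ||
      fit_reduced$ar_order > fit_full$ar_order) {
    stop("models are not nested in their random/correlation structure",
         call. = FALSE)
  }
  if (fit_full$n_obs != fit_reduced$n_obs) {
    stop("fits use different data", call. = FALSE)
  }
  if (fit_full$method != fit_reduced$method) {
    stop("fits use different estimation methods", call. = FALSE)
  }
  if (fit_full$method != "ML") {
    warning("likelihood-ratio comparison of REML fits; refit with method = 'ML'")
  }
  npar <- function(f) {
    q <- length(f$random_spec)
    q * (q + 1) / 2 + f$ar_order
  }
  df <- npar(fit_full) - npar(fit_reduced)
  statistic <- max(0, 2 * (fit_full$logLik - fit_reduced$logLik))
  p <- if (df == 0) 1 else stats::pchisq(statistic, df, lower.tail = FALSE)
  list(statistic = statistic, df = df, p_value = p)
}

#' Factual and counterfactual population-level predictions
#'
#' Monthly fixed-effects predictions with and without the communication
#' terms: the factual curve uses all terms, the counterfactual zeroes the
#' level-change and slope-change contributions (continuing the pre-warning
#' trend), and both average calendar-month effects as observed. Predictions
#' are population-level (no practice effects), averaged over the design rows
#' of each month.
#'
#' @param fit an `its_fit`.
#' @param design the design tibble the fit used (or new data in the same
#'   coding).
#' @return a tibble: `period`, `t`, `n`, `factual`, `counterfactual`.
#' @export
predict_counterfactual <- function(fit, design) {
  X <- stats::model.matrix(model_formula(fit$seasonality), data = design)
  beta_full <- fit$coefficients$estimate
  names(beta_full) <- fit$coefficients$term
  beta_full <- beta_full[colnames(X)]
  factual <- as.numeric(X %*% beta_full)
  cf_adjust <- beta_full["post"] * design$post + beta_full["s"] * design$s
  tibble::tibble(period = design$period, t = design$t,
                 factual = factual, counterfactual = factual - cf_adjust) |>
    dplyr::group_by(.data$period, .data$t) |>
    dplyr::summarise(n = dplyr::n(),
                     factual = mean(.data$factual),
                     counterfactual = mean(.data$counterfactual),
                     .groups = "drop") |>
    dplyr::arrange(.data$t)
}
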