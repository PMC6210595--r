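#' Classify practices by their post-warning level and slope changes
#'
#' Labels each practice's response to the safety communication from its
#' level-change and slope-change BLUPs. A 95% interval
#' `b_hat +/- 1.96 * SE_cond` is formed from the conditional (posterior)
#' standard error of each practice effect; a practice is a `decrease` when
#' the upper bound is below zero, an `increase` when the lower bound is above
#' zero, and `no_change` otherwise. Because BLUPs are shrunken towards zero,
#' this classification is conservative under the null of no practice-specific
#' change.
#'
#' @param fit an `its_fit` from [fit_segmented()] whose random effects
#'   include `level_change` and/or `slope_change`; alternatively a tibble in
#'   the shape of `fit$blups`.
#' @param level confidence level of the interval.
#' @return a tibble with, per practice, the BLUP, conditional SE, CI bounds,
#'   and class (`decrease`/`no_change`/`increase`) for each available change
#'   dimension (`level_class`, `slope_class`).
#' @seealso [response_counts()], [fit_predictors()]
#' @export
classify_practices <- function(fit, level = 0.95) {
  blups <- if (inherits(fit, "its_fit")) fit$blups else fit
  if (is.null(blups)) stop("fit has no practice random effects", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- tibble::tibble(practice_id = blups$practice_id)
  any_dim <- FALSE
  for (dim in c("level_change", "slope_change")) {
    bcol <- paste0("b_", dim)
    scol <- paste0("se_", dim)
    if (!bcol %in% names(blups)) next
    if (!scol %in% names(blups) || anyNA(blups[[scol]])) {
      stop("missing conditional SEs for ", dim, call. = FALSE)
    }
    any_dim <- TRUE
    b <- blups[[bcol]]; se <- blups[[scol]]
    lo <- b - z * se; hi <- b + z * se
    cls <- dplyr::case_when(hi < 0 ~ "decrease", lo > 0 ~ "increase",
                            TRUE ~ "no_change")
    prefix <- if (dim == "level_change") "level" else "slope"
    out[[paste0("b_", dim)]] <- b
    out[[paste0("se_", dim)]] <- se
    out[[paste0(prefix, "_ci_low")]] <- lo
    out[[paste0(prefix, "_ci_high")]] <- hi
    out[[paste0(prefix, "_class")]] <-
      factor(cls, levels = c("decrease", "no_change", "increase"))
  }
  if (!any_dim) {
    stop("fit contains neither level-change nor slope-change random effects",
         call. = FALSE)
  }
  out
}

#' Responder counts table
#'
#' Cross-tabulates the classification of [classify_practices()] into the
#' conventional three-row shape (decrease / no change / increase, with
#' percentages) for the level-change and slope-change dimensions.
#'
#' @param classes output of [classify_practices()].
#' @return a tibble: `class`, and `n`/`pct` per available dimension.
#' @export
response_counts <- function(classes) {
  out <- tibble::tibble(class = c("decrease", "no_change", "increase"))
  for (prefix in c("level", "slope")) {
    col <- paste0(prefix, "_class")
    if (!col %in% names(classes)) next
    tab <- table(classes[[col]])
    out[[paste0(prefix, "_n")]] <- as.integer(tab[out$class])
    out[[paste0(prefix, "_pct")]] <- 100 * as.numeric(tab[out$class]) / nrow(classes)
  }
  out
}

#' Practice characteristics as predictors of a prescribing decrease
#'
#' Multivariable logistic regression of a binary responder outcome (a
#' significant decrease in level or in slope, versus everything else) on the
#' practice characteristics, entered jointly. Continuous characteristics are
#' standardized (z-scored over the included practices) so odds ratios are per
#' SD; binary characteristics stay on their natural 0/1 scale unless
#' `standardize_binary = TRUE`. Practices with any missing characteristic are
#' dropped from this model only (their count is attached as attribute
#' `n_dropped`).
#'
#' @param classes output of [classify_practices()].
#' @param profiles practice characteristics (see [read_profiles()]).
#' @param outcome which decrease to model.
#' @param covariates character vector of profile columns to enter.
#' @param standardize z-score continuous covariates.
#' @param standardize_binary also z-score binary covariates.
#' @param conf_level Wald CI level.
#' @return a tibble with one row per covariate: `term`, `log_or`, `se`,
#'   `or`, `ci_low`, `ci_high`, `p`. Attributes: `n`, `n_events`,
#'   `n_dropped`, `outcome`, `scaling` (means/SDs used), `separation`
#'   (logical flag). The intercept row is retained with `term =
#'   "(Intercept)"`.
#' @export
fit_predictors <- function(classes, profiles,
                           outcome = c("decrease_level", "decrease_slope"),
                           covariates = predictor_fields,
                           standardize = TRUE, standardize_binary = FALSE,
                           conf_level = 0.95) {
  outcome <- match.arg(outcome)
  col <- if (outcome == "decrease_level") "level_class" else "slope_class"
  if (!col %in% names(classes)) {
    stop("classes lack ", col, " for outcome ", outcome, call. = FALSE)
  }
  dat <- dplyr::inner_join(
    dplyr::select(classes, "practice_id", dplyr::all_of(col)),
    dplyr::select(profiles, "practice_id", dplyr::all_of(covariates)),
    by = "practice_id"
  )
  complete <- stats::complete.cases(dat)
  n_dropped <- sum(!complete)
  dat <- dat[complete, ]
  y <- as.integer(dat[[col]] == "decrease")
  if (all(y == y[1])) stop("outcome is constant; cannot fit predictors", call. = FALSE)
  if (sum(y) < 10) {
    warning("fewer than 10 decrease events (", sum(y), "); estimates unstable")
  }

  xmat <- dat[covariates]
  scaling <- tibble::tibble(term = covariates, center = 0, scale = 1)
  for (j in seq_along(covariates)) {
    v <- xmat[[j]]
    is_bin <- is.logical(v) || all(v %in% c(0, 1))
    v <- as.numeric(v)
    if (standardize && (!is_bin || standardize_binary)) {
      mu <- mean(v); sg <- stats::sd(v)
      if (sg == 0) stop("covariate ", covariates[j], " is constant", call. = FALSE)
      v <- (v - mu) / sg
      scaling$center[j] <- mu; scaling$scale[j] <- sg
    }
    xmat[[j]] <- v
  }
  mf <- cbind(data.frame(.y = y), xmat)
  m <- stats::glm(.y ~ ., data = mf, family = stats::binomial(),
                  control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  est <- stats::coef(m)
  se <- sqrt(diag(stats::vcov(m)))
  separation <- any(abs(est[-1]) > 15) ||
    all(m$fitted.values < 1e-8 | m$fitted.values > 1 - 1e-8)
  if (separation) warning("possible separation in predictor model")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    term = names(est), log_or = unname(est), se = unname(se),
    or = exp(unname(est)),
    ci_low = exp(unname(est - z * se)), ci_high = exp(unname(est + z * se)),
    p = 2 * stats::pnorm(-abs(unname(est) / unname(se)))
  )
  attr(out, "n") <- nrow(dat)
  attr(out, "n_events") <- sum(y)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "outcome") <- outcome
  attr(out, "scaling") <- scaling
  attr(out, "separation") <- separation
  out
}
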