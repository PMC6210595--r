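#' Configuration for the synthetic prescribing panel generator
#'
#' Defines the generative model mirrored by the segmented mixed model that
#' [fit_segmented()] estimates. For practice `p` in month `t` (months coded
#' relative to the month before the communication, which is `t = 0`), the
#' latent percentage share is
#'
#' \deqn{\mu_{pt} = (\beta_0 + b_{0p}) + (\beta_1 + b_{1p}) t +
#'   (\beta_2 + b_{2p}) \mathrm{post}_t + (\beta_3 + b_{3p}) s_t +
#'   \gamma_{m(t)} + \varepsilon_{pt}}
#'
#' with `post_t = 1` from the month after the communication (`t >= 2`),
#' `s_t = (t - 2) post_t`, practice effects `(b_0..b_3) ~ MVN(0, G)`,
#' calendar-month effects `gamma` constrained to sum to zero, and
#' `epsilon` a stationary AR(2) process with innovation SD `sigma_w`. The
#' communication month itself (`t = 1`) is generated from the pre-period
#' line, consistent with treating it as a transition month. Counts are then
#' `class_items ~ Poisson(lambda_p)` with `lambda_p` lognormal with mean
#' `lambda_mean`, and `focal_items ~ Binomial(class_items, mu/100)` with
#' `mu` clamped to `[0, 100]` (the clamp rate is recorded in the truth
#' record and stays well below 1% under defaults).
#'
#' Defaults plant the headline structural estimates of the motivating
#' analysis (level 8.30, trend 0.294, level change -0.023, trend change
#' -0.036, all in percentage points) over the January 2014 to March 2017
#' window with a September 2015 communication. The default random-effect
#' correlation puts 0.8 between the intercept and pre-period slope: early in
#' the window the drug is new, so practices with low shares are late
#' adopters with flatter growth, which also keeps latent percentages
#' non-negative.
#'
#' Practice characteristics are drawn to match published practice
#' descriptives (list size median ~6600, ~17% patients 65+, median 4 GP
#' FTEs, ~26% of practices with a registrar, ...). `delta_level` /
#' `delta_slope` are named vectors linking standardized characteristics to a
#' shift (in percentage points) of the practice's level-change / slope-change
#' effect, so responder status can be made to depend on covariates with known
#' direction; both default to zero (no association).
#'
#' @param n_practices number of practices.
#' @param start,end first and last `YYYYMM` month of the window.
#' @param dhpc_month `YYYYMM` month the safety communication is issued.
#' @param beta numeric length 4: level at `t = 0`, pre slope (pp/month),
#'   level change, slope change.
#' @param gamma length-12 calendar-month effects (January first), summing to
#'   zero.
#' @param sigma_b length-4 SDs of the practice effects `(b0, b1, b2, b3)`.
#' @param corr_b 4x4 correlation matrix of the practice effects.
#' @param rho AR(2) coefficients of the within-practice noise; must be
#'   stationary.
#' @param sigma_w innovation SD of the AR(2) noise (0 disables it).
#' @param lambda_mean mean class items per practice-month.
#' @param lambda_sdlog lognormal SD (log scale) of the per-practice mean.
#' @param total_rate expected non-class items per class item's lambda
#'   (total items = class + Poisson(total_rate * lambda_p)).
#' @param delta_level,delta_slope named numeric vectors over profile fields
#'   (see [read_profiles()]) shifting b2 / b3 by `delta' z_p` with `z_p` the
#'   standardized covariates.
#' @param seed integer seed; all randomness derives from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_practices = 500,
                       start = 201401, end = 201703, dhpc_month = 201509,
                       beta = c(level = 8.30, slope = 0.294,
                                level_change = -0.023, slope_change = -0.036),
                       gamma = 0.3 * cos(2 * pi * (0:11) / 12),
                       sigma_b = c(1.5, 0.05, 0.15, 0.02),
                       corr_b = default_corr_b(),
                       rho = c(0.3, 0.1), sigma_w = 0.5,
                       lambda_mean = 76, lambda_sdlog = 0.5,
                       total_rate = 80,
                       delta_level = NULL, delta_slope = NULL,
                       seed = 1L) {
  stopifnot(length(beta) == 4, length(gamma) == 12, length(sigma_b) == 4,
            length(rho) == 2, sigma_w >= 0, lambda_mean > 0, n_practices >= 1)
  beta <- stats::setNames(as.numeric(beta),
                          c("level", "slope", "level_change", "slope_change"))
  if (abs(sum(gamma)) > 1e-8) {
    stop("seasonal effects `gamma` must sum to zero", call. = FALSE)
  }
  if (!(rho[2] > -1 && rho[2] < 1 && rho[1] + rho[2] < 1 && rho[2] - rho[1] < 1)) {
    stop("AR(2) coefficients are not stationary", call. = FALSE)
  }
  corr_b <- as.matrix(corr_b)
  stopifnot(dim(corr_b) == c(4, 4), all(abs(diag(corr_b) - 1) < 1e-12))
  G <- diag(sigma_b) %*% corr_b %*% diag(sigma_b)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    stop("random-effect covariance is not positive semi-definite", call. = FALSE)
  }
  if (month_index(dhpc_month) - month_index(start) < 2 ||
      month_index(end) - month_index(dhpc_month) < 2) {
    stop("`dhpc_month` too close to the window boundary", call. = FALSE)
  }
  structure(
    list(n_practices = as.integer(n_practices), start = as.integer(start),
         end = as.integer(end), dhpc_month = as.integer(dhpc_month),
         beta = beta, gamma = as.numeric(gamma),
         sigma_b = as.numeric(sigma_b), corr_b = corr_b, G = G,
         rho = as.numeric(rho), sigma_w = sigma_w,
         lambda_mean = lambda_mean, lambda_sdlog = lambda_sdlog,
         total_rate = total_rate,
         delta_level = delta_level, delta_slope = delta_slope,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_corr_b <- function() {
  m <- diag(4)
  m[1, 2] <- m[2, 1] <- 0.8
  m
}

# covariates entering delta shifts and the predictor model
predictor_fields <- c("gp_fte", "pct_gp_female", "pct_gp_45plus",
                      "has_registrar", "list_size", "pct_patients_female",
                      "pct_patients_65plus", "qof_overall_pct",
                      "hypertension_prevalence", "dementia_prevalence",
                      "imd_decile")

rtrunc_norm <- function(n, mean, sd, lo, hi) pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

simulate_profiles <- function(n) {
  list_size <- round(stats::rlnorm(n, log(6613), 0.66))
  # patients per FTE is tightly regulated around ~1700, so FTE count scales
  # with list size rather than varying independently
  per_fte <- stats::rlnorm(n, log(1700), 0.25)
  tibble::tibble(
    practice_id = sprintf("P%05d", seq_len(n)),
    list_size = list_size,
    pct_patients_65plus = rtrunc_norm(n, 16.8, 6.5, 0, 100),
    pct_patients_female = rtrunc_norm(n, 49.9, 2.3, 0, 100),
    gp_fte = pmax(round(list_size / per_fte, 1), 0.5),
    pct_gp_female = rtrunc_norm(n, 46.5, 25.9, 0, 100),
    pct_gp_45plus = rtrunc_norm(n, 56.2, 28.4, 0, 100),
    has_registrar = stats::runif(n) < 0.255,
    qof_overall_pct = rtrunc_norm(n, 94.5, 4.5, 0, 100),
    hypertension_prevalence = rtrunc_norm(n, 13.8, 2.8, 0, 100),
    dementia_prevalence = rtrunc_norm(n, 0.75, 0.35, 0, 100),
    imd_decile = sample.int(10, n, replace = TRUE)
  )
}

# standardized covariate matrix for delta shifts / predictor checks;
# binary covariates stay on the 0/1 scale
standardize_covariates <- function(profiles, fields = predictor_fields,
                                   standardize_binary = FALSE) {
  z <- sapply(fields, function(f) {
    v <- as.numeric(profiles[[f]])
    if (is.logical(profiles[[f]]) && !standardize_binary) return(v)
    s <- stats::sd(v)
    if (is.na(s) || s == 0) return(v * 0)
    (v - mean(v)) / s
  })
  matrix(z, nrow = nrow(profiles), dimnames = list(NULL, fields))
}

# stationary AR(2) noise, one series per practice (rows)
simulate_ar2 <- function(n, t_len, rho, sigma_w) {
  if (sigma_w == 0) return(matrix(0, n, t_len))
  if (all(rho == 0)) return(matrix(stats::rnorm(n * t_len, sd = sigma_w), n, t_len))
  t(vapply(seq_len(n), function(i) {
    as.numeric(stats::arima.sim(list(ar = rho), n = t_len, sd = sigma_w))
  }, numeric(t_len)))
}

#' Simulate a practice prescribing panel with known ground truth
#'
#' Draws a full practice-month panel, a matching characteristics table and a
#' truth record from the generative model described in [sim_config()]. All
#' randomness derives from `config$seed` through a fixed sub-seed ladder
#' (stage `k` of the draw reseeds with `seed * 10 + k`; stage 1: profiles,
#' 2: practice effects, 3: AR noise, 4: counts), so each stage is
#' independently reproducible, the whole draw is deterministic given the
#' seed, and simulations at distinct seeds never share a stage stream.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements
#'   * `panel`: practice-month counts tibble (as from [read_prescribing()]);
#'   * `profiles`: practice characteristics tibble;
#'   * `truth`: list with the practice effects `b` (n x 4 matrix, after any
#'     `delta` shift), `lambda`, the latent `mu` and noise `eps` matrices
#'     (practices x months), the clamp rate, and the configuration.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_practices
  periods <- period_seq(config$start, config$end)
  t_len <- length(periods)
  t_code <- month_index(periods) - month_index(config$dhpc_month) + 1L
  post <- as.integer(t_code >= 2L)
  s <- (t_code - 2L) * post
  gam <- config$gamma[month_of_year(periods)]
  stage_seed <- function(k) {
    as.integer((as.numeric(config$seed) * 10 + k) %% 2147483647)
  }

  set.seed(stage_seed(1))
  profiles <- simulate_profiles(n)

  set.seed(stage_seed(2))
  b <- matrix(stats::rnorm(n * 4), n, 4) %*% chol_psd(config$G)
  colnames(b) <- c("b_level", "b_slope", "b_level_change", "b_slope_change")
  z <- standardize_covariates(profiles)
  if (!is.null(config$delta_level)) {
    b[, 3] <- b[, 3] + as.numeric(z[, names(config$delta_level), drop = FALSE] %*%
                                    config$delta_level)
  }
  if (!is.null(config$delta_slope)) {
    b[, 4] <- b[, 4] + as.numeric(z[, names(config$delta_slope), drop = FALSE] %*%
                                    config$delta_slope)
  }

  set.seed(stage_seed(3))
  eps <- simulate_ar2(n, t_len, config$rho, config$sigma_w)

  beta <- config$beta
  mu <- outer(b[, 1] + beta[1], rep(1, t_len)) +
    outer(beta[2] + b[, 2], t_code) +
    outer(beta[3] + b[, 3], post) +
    outer(beta[4] + b[, 4], s) +
    matrix(gam, n, t_len, byrow = TRUE) + eps
  clamp_rate <- mean(mu < 0 | mu > 100)
  p <- pmin(pmax(mu, 0), 100) / 100

  set.seed(stage_seed(4))
  meanlog <- log(config$lambda_mean) - config$lambda_sdlog^2 / 2
  lambda <- stats::rlnorm(n, meanlog, config$lambda_sdlog)
  class_items <- matrix(stats::rpois(n * t_len, rep(lambda, t_len)), n, t_len)
  focal_items <- matrix(
    stats::rbinom(n * t_len, as.vector(class_items), as.vector(p)), n, t_len
  )
  other_items <- matrix(
    stats::rpois(n * t_len, rep(lambda * config$total_rate, t_len)), n, t_len
  )

  panel <- tibble::tibble(
    practice_id = rep(profiles$practice_id, each = t_len),
    period = rep(periods, n),
    focal_items = as.vector(t(focal_items)),
    class_items = as.vector(t(class_items)),
    total_items = as.vector(t(class_items + other_items))
  )
  validate_panel(panel)
  list(
    panel = panel,
    profiles = profiles,
    truth = list(
      b = tibble::as_tibble(cbind(tibble::tibble(practice_id = profiles$practice_id),
                                  tibble::as_tibble(b))),
      lambda = lambda, mu = mu, eps = eps,
      clamp_rate = clamp_rate, periods = periods, config = config
    )
  )
}

# Cholesky-like factor tolerating a PSD (possibly singular) matrix
chol_psd <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% diag(sqrt(v), nrow = length(v)))
}

#' Write a synthetic fixture to disk
#'
#' Materialises a simulated panel as the CSV files [read_prescribing()] and
#' [read_profiles()] consume, plus a JSON truth record. Sizes:
#' `tiny` (10 practices x 8 months, for unit tests), `small` (200 practices
#' over the full window, with 5 practices deliberately planted to violate one
#' exclusion rule each: small list, low and high list-per-FTE, zero FTE, and
#' a low-prescribing month inside the exclusion window), and `paper_like`
#' (7408 practices x 39 months; slow and large).
#'
#' @param dir output directory (created if needed).
#' @param size fixture size.
#' @param seed integer seed.
#' @return invisibly, a named list of the file paths written
#'   (`prescribing`, `profiles`, `truth`).
#' @export
make_fixture <- function(dir, size = c("tiny", "small", "paper_like"), seed = 1L) {
  size <- match.arg(size)
  cfg <- switch(size,
    tiny = sim_config(n_practices = 10, start = 201501, end = 201508,
                      dhpc_month = 201504, seed = seed),
    small = sim_config(n_practices = 200, seed = seed),
    paper_like = sim_config(n_practices = 7408, sigma_b = c(6.0, 0.08, 0.15, 0.02),
                            seed = seed)
  )
  sim <- simulate_panel(cfg)
  panel <- sim$panel
  profiles <- sim$profiles

  if (size == "small") {
    # guarantee exactly five violators: clamp everyone safely inside the
    # rules first, then plant one violation per rule in the first five
    profiles$list_size <- pmax(profiles$list_size, 800)
    profiles$gp_fte <- pmin(pmax(profiles$gp_fte, profiles$list_size / 4500),
                            profiles$list_size / 550)
    ids <- profiles$practice_id[1:5]
    profiles$list_size[1] <- 700                       # min_list
    profiles$list_size[2] <- 2000; profiles$gp_fte[2] <- 5    # 400 per FTE
    profiles$list_size[3] <- 6000; profiles$gp_fte[3] <- 1    # 6000 per FTE
    profiles$gp_fte[4] <- 0                            # per-FTE undefined
    low <- panel$practice_id == ids[5] & panel$period == cfg$dhpc_month
    panel$total_items[low] <- 50                       # min_items
    panel$class_items[low] <- pmin(panel$class_items[low], 50)
    panel$focal_items[low] <- pmin(panel$focal_items[low], panel$class_items[low])
    attr(panel, "planted_exclusions") <- ids
  }

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    prescribing = file.path(dir, "prescribing.csv"),
    profiles = file.path(dir, "characteristics.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_prescribing(panel, paths$prescribing)
  write_profiles(profiles, paths$profiles)
  truth <- sim$truth
  jsonlite::write_json(
    list(
      size = size, seed = seed,
      beta = as.list(truth$config$beta),
      gamma = truth$config$gamma, sigma_b = truth$config$sigma_b,
      rho = truth$config$rho, sigma_w = truth$config$sigma_w,
      clamp_rate = truth$clamp_rate,
      b = truth$b, lambda = truth$lambda,
      planted_exclusions = if (size == "small") profiles$practice_id[1:5]
    ),
    paths$truth, auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
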