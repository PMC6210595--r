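# Independent oracles and small fixture builders used across tests.
# These deliberately re-derive quantities with plain loops / enumeration,
# not through the package's own code paths.

# Brute-force SCV: trim on shares (inclusive type-7 percentile bounds),
# expected counts proportional to class counts, Poisson correction, x100.
oracle_scv <- function(focal, class_items, trim = c(5, 95)) {
  share <- 100 * focal / class_items
  bounds <- quantile(share, trim / 100, type = 7, names = FALSE)
  keep <- share >= bounds[1] & share <= bounds[2]
  o <- focal[keep]
  cl <- class_items[keep]
  e <- cl * sum(o) / sum(cl)
  k <- length(o)
  total <- 0
  for (i in seq_len(k)) {
    total <- total + ((o[i] - e[i]) / e[i])^2 - 1 / e[i]
  }
  raw <- 100 * total / k
  max(0, raw)
}

# Exact two-sided rank-sum p-value by full enumeration of all
# choose(n + m, n) group assignments, mid-ranks, deviation-from-expectation
# two-sided convention.
oracle_rank_sum_p <- function(x, y) {
  n <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)])
  e_w <- n * sum(r) / length(r)
  sets <- utils::combn(length(r), n)
  w_all <- apply(sets, 2, function(idx) sum(r[idx]))
  mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-9)
}

# one-month share panel with random counts
random_month_panel <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(4:12, 1)
  cls <- rpois(n, 60) + 1
  focal <- rbinom(n, cls, runif(1, 0.02, 0.3))
  panel <- tibble::tibble(
    practice_id = sprintf("R%03d", seq_len(n)),
    period = 201509L,
    focal_items = focal, class_items = cls,
    total_items = cls + rpois(n, 4000)
  )
  compute_share(panel)
}

# hand-built share panel: one row per practice x period with given shares
manual_share_panel <- function(practice_id, period, share, class_items = 100) {
  panel <- tibble::tibble(
    practice_id = practice_id,
    period = as.integer(period),
    class_items = class_items,
    focal_items = as.integer(round(share / 100 * class_items)),
    total_items = class_items + 5000L
  )
  compute_share(panel)
}

# minimal blups table for classification tests
fake_blups <- function(b_level, se_level, b_slope = NULL, se_slope = NULL) {
  out <- tibble::tibble(
    practice_id = sprintf("F%03d", seq_along(b_level)),
    b_level_change = b_level, se_level_change = se_level
  )
  if (!is.null(b_slope)) {
    out$b_slope_change <- b_slope
    out$se_slope_change <- se_slope
  }
  out
}

# default profile table for exclusion tests: everything comfortably inside
# the inclusion rules
ok_profile <- function(practice_id, list_size = 6000, gp_fte = 4) {
  tibble::tibble(
    practice_id = practice_id, list_size = list_size,
    pct_patients_65plus = 17, pct_patients_female = 50, gp_fte = gp_fte,
    pct_gp_female = 47, pct_gp_45plus = 56, has_registrar = FALSE,
    qof_overall_pct = 95, hypertension_prevalence = 14,
    dementia_prevalence = 0.8, imd_decile = 5L
  )
}

# constant-count panel over a period range
flat_panel <- function(practice_id, from = 201401, to = 201703,
                       focal = 10L, class_items = 100L, total = 6000L) {
  tidyr::expand_grid(practice_id = practice_id,
                     period = period_seq(from, to)) |>
    dplyr::mutate(focal_items = focal, class_items = class_items,
                  total_items = total)
}
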