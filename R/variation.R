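#' Systematic component of variation for one month
#'
#' Estimates the systematic (non-random) component of between-practice
#' variation in the focal drug's share for a single month, on the
#' McPherson-style x100 scale with a Poisson sampling correction. With
#' observed focal counts `O_i` and expected counts
#' `E_i = class_i * (sum O / sum class)` over the included practices,
#'
#' \deqn{SCV = \frac{100}{k} \sum_i \left[ \left(\frac{O_i - E_i}{E_i}\right)^2
#'   - \frac{1}{E_i} \right]}
#'
#' Practices are first restricted to those whose share lies within the
#' month's 5th-95th percentile band (inclusive; type-7 quantiles), following
#' the convention of trimming extreme prescribers before assessing
#' systematic variation. A negative raw value (sampling noise exceeding the
#' Poisson expectation) is truncated to zero; the raw value is retained.
#' Values are banded as low (< 3), moderate (3-5.4), high (5.4-10) or very
#' high (> 10).
#'
#' @param share_panel a share panel from [compute_share()].
#' @param month `YYYYMM` month.
#' @param trim percentile bounds (inclusive) of the share distribution used
#'   to select practices; `c(0, 100)` disables trimming.
#' @return a one-row tibble: `period`, `scv`, `scv_raw`, `k` (practices
#'   used), `trim_lo`, `trim_hi` (share bounds), `band`, `n_dropped`
#'   (practices with undefined share or zero expected count).
#' @export
scv_month <- function(share_panel, month, trim = c(5, 95)) {
  rows <- dplyr::filter(share_panel, .data$period == month, !is.na(.data$share_pct))
  n_undef <- sum(share_panel$period == month) - nrow(rows)
  if (nrow(rows) < 2) stop("need >= 2 practices with defined share", call. = FALSE)
  bounds <- stats::quantile(rows$share_pct, trim / 100, type = 7, names = FALSE)
  keep <- rows$share_pct >= bounds[1] & rows$share_pct <= bounds[2]
  rows <- rows[keep, ]
  o <- rows$focal_items
  cl <- rows$class_items
  pooled <- sum(o) / sum(cl)
  if (pooled == 0) stop("overall share is zero; SCV undefined", call. = FALSE)
  e <- cl * pooled
  drop_e <- e == 0
  o <- o[!drop_e]; e <- e[!drop_e]
  k <- length(o)
  raw <- (100 / k) * sum(((o - e) / e)^2 - 1 / e)
  scv <- max(0, raw)
  tibble::tibble(
    period = as.integer(month), scv = scv, scv_raw = raw, k = k,
    trim_lo = bounds[1], trim_hi = bounds[2],
    band = scv_band(scv), n_dropped = n_undef + sum(drop_e)
  )
}

scv_band <- function(scv) {
  cut(scv, breaks = c(-Inf, 3, 5.4, 10, Inf),
      labels = c("low", "moderate", "high", "very high"), right = FALSE) |>
    as.character()
}

#' Monthly SCV series
#'
#' @inheritParams scv_month
#' @param months `YYYYMM` months to evaluate (default: all panel months).
#' @return a tibble with one [scv_month()] row per month.
#' @export
scv_series <- function(share_panel, months = NULL, trim = c(5, 95)) {
  if (is.null(months)) months <- sort(unique(share_panel$period))
  dplyr::bind_rows(lapply(months, function(m) scv_month(share_panel, m, trim)))
}

#' Compare SCV in the windows before and after a safety communication
#'
#' Computes monthly SCV values for the `w` months strictly before and the
#' `w` months strictly after `dhpc_month` (the communication month itself
#' belongs to neither window) and compares the two sets of monthly values
#' with the two-sided rank-sum test of [exact_rank_sum_test()] (exact for
#' the default window sizes).
#'
#' @inheritParams scv_month
#' @param dhpc_month `YYYYMM` communication month.
#' @param w window length in months on each side.
#' @return a list: `median_pre`, `median_post`, `p_value`, plus the two SCV
#'   series (`pre`, `post`).
#' @export
scv_window_compare <- function(share_panel, dhpc_month, w = 6, trim = c(5, 95)) {
  d <- month_index(dhpc_month)
  pre_months <- index_to_period(seq(d - w, d - 1))
  post_months <- index_to_period(seq(d + 1, d + w))
  have <- unique(share_panel$period)
  if (!all(c(pre_months, post_months) %in% have)) {
    stop("panel does not span ", w, " months on each side of the communication",
         call. = FALSE)
  }
  pre <- scv_series(share_panel, pre_months, trim)
  post <- scv_series(share_panel, post_months, trim)
  test <- exact_rank_sum_test(pre$scv, post$scv)
  list(median_pre = stats::median(pre$scv),
       median_post = stats::median(post$scv),
       p_value = test$p.value, pre = pre, post = post)
}

#' Standardized prescribing ratios
#'
#' A practice's monthly share divided by the pooled share across all
#' practices that month (`100 * sum O / sum class`, over practices with a
#' defined share). Ratios above 1 indicate above-average prescribing of the
#' focal drug. The class-weighted mean ratio is exactly 1 in every month by
#' construction.
#'
#' @inheritParams scv_month
#' @param months months to evaluate (default all).
#' @return a tibble `practice_id`, `period`, `share_pct`, `pooled_share`,
#'   `ratio` (NA where the share is undefined).
#' @export
standardized_ratios <- function(share_panel, months = NULL) {
  if (is.null(months)) months <- sort(unique(share_panel$period))
  rows <- dplyr::filter(share_panel, .data$period %in% months)
  pooled <- rows |>
    dplyr::filter(!is.na(.data$share_pct)) |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(
      pooled_share = 100 * sum(.data$focal_items) / sum(.data$class_items),
      .groups = "drop"
    )
  if (any(pooled$pooled_share == 0)) {
    stop("pooled share is zero in month(s) ",
         paste(pooled$period[pooled$pooled_share == 0], collapse = ", "),
         call. = FALSE)
  }
  rows |>
    dplyr::left_join(pooled, by = "period") |>
    dplyr::transmute(.data$practice_id, .data$period, .data$share_pct,
                     .data$pooled_share,
                     ratio = .data$share_pct / .data$pooled_share)
}

#' Rolling six-month prescribing ratios relative to a reference month
#'
#' For each practice and month `m`, the mean share over the previous
#' `window` months (`m - window + 1 .. m`, requiring all of them defined)
#' divided by that practice's share in `ref_month`. Practices whose
#' reference-month share is zero or undefined are excluded. The companion
#' percentile table gives, per month, the deciles and the 1st-9th bottom and
#' top percentiles (type-7 quantiles) of the ratios.
#'
#' @inheritParams scv_month
#' @param ref_month `YYYYMM` reference month.
#' @param window rolling window length in months.
#' @return a list with `ratios` (tibble `practice_id`, `period`,
#'   `rolling_mean`, `ratio`) and `percentiles` (tibble `period`, `prob`,
#'   `value`).
#' @export
rolling_ratio_distribution <- function(share_panel, ref_month, window = 6) {
  months <- sort(unique(share_panel$period))
  if (!ref_month %in% months) stop("`ref_month` not in panel", call. = FALSE)
  wide <- share_panel |>
    dplyr::select("practice_id", "period", "share_pct") |>
    tidyr::pivot_wider(names_from = "period", values_from = "share_pct")
  mat <- as.matrix(wide[, -1])
  colnames(mat) <- names(wide)[-1]
  ref <- as.numeric(mat[, as.character(ref_month)])
  ok <- !is.na(ref) & ref > 0
  if (!any(ok)) stop("reference-month share undefined or zero for all practices",
                     call. = FALSE)
  mat <- mat[ok, , drop = FALSE]
  ids <- wide$practice_id[ok]
  eval_months <- months[seq_along(months) >= window]
  roll <- sapply(eval_months, function(m) {
    cols <- as.character(index_to_period(seq(month_index(m) - window + 1,
                                             month_index(m))))
    rowMeans(mat[, cols, drop = FALSE])   # NA if any month undefined
  })
  roll <- matrix(roll, nrow = length(ids))
  ratios <- tibble::tibble(
    practice_id = rep(ids, times = length(eval_months)),
    period = rep(eval_months, each = length(ids)),
    rolling_mean = as.vector(roll),
    ratio = as.vector(roll) / rep(ref[ok], times = length(eval_months))
  )
  probs <- c(1:9, seq(10, 90, 10), 91:99) / 100
  percentiles <- ratios |>
    dplyr::filter(!is.na(.data$ratio)) |>
    dplyr::group_by(.data$period) |>
    dplyr::reframe(prob = probs,
                   value = stats::quantile(.data$ratio, probs, type = 7,
                                           names = FALSE))
  list(ratios = ratios, percentiles = percentiles)
}
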