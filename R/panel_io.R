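#' Read an NHS-style practice prescribing extract
#'
#' Reads a monthly prescribing CSV in the NHS Digital practice-prescribing
#' dialect (columns `PRACTICE`, `PERIOD`, `BNF_CODE`, `BNF_NAME`, `ITEMS`;
#' `BNF_NAME` is ignored) and aggregates it to one row per practice-month with
#' counts for a focal product, its drug class, and all items. BNF codes are
#' hierarchical, so products are matched by code prefix: `focal_items` sums
#' items whose code starts with `focal_code`, `class_items` those starting
#' with `class_code`, and `total_items` everything. Practice-months absent
#' from the file but inside the study window are filled in as zero-count rows.
#'
#' @param path path to the prescribing CSV.
#' @param focal_code BNF code prefix of the focal product
#'   (default mirabegron, `"0704020AE"`).
#' @param class_code BNF code prefix of the containing drug class
#'   (default urinary frequency / OAB drugs, `"070402"`). Must itself be a
#'   prefix of `focal_code`.
#' @param window optional length-2 vector of `YYYYMM` periods bounding the
#'   study window; defaults to the range observed in the file.
#' @return a tibble with columns `practice_id`, `period` (integer `YYYYMM`),
#'   `focal_items`, `class_items`, `total_items`, one row per practice-month
#'   on the complete practice-by-window grid.
#' @seealso [compute_share()], [apply_exclusions()], [write_prescribing()]
#' @export
read_prescribing <- function(path, focal_code = "0704020AE",
                             class_code = "070402", window = NULL) {
  if (!startsWith(focal_code, class_code)) {
    stop("`focal_code` must extend `class_code` as a BNF prefix", call. = FALSE)
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      PRACTICE = readr::col_character(),
      PERIOD = readr::col_character(),
      BNF_CODE = readr::col_character(),
      ITEMS = readr::col_double(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  need <- c("PRACTICE", "PERIOD", "BNF_CODE", "ITEMS")
  if (!all(need %in% names(raw))) {
    stop("prescribing file lacks columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) > 0 && any(raw$ITEMS < 0, na.rm = TRUE)) {
    stop("negative ITEMS values in prescribing file", call. = FALSE)
  }
  idx <- if (nrow(raw) > 0) month_index(raw$PERIOD) else integer(0)

  agg <- tibble::tibble(
    practice_id = raw$PRACTICE,
    period = if (nrow(raw) > 0) index_to_period(idx) else integer(0),
    items = raw$ITEMS,
    is_focal = startsWith(raw$BNF_CODE, focal_code),
    is_class = startsWith(raw$BNF_CODE, class_code)
  ) |>
    dplyr::group_by(.data$practice_id, .data$period) |>
    dplyr::summarise(
      focal_items = sum(.data$items[.data$is_focal]),
      class_items = sum(.data$items[.data$is_class]),
      total_items = sum(.data$items),
      .groups = "drop"
    )

  if (is.null(window)) {
    if (nrow(agg) == 0) stop("empty prescribing file and no `window` given", call. = FALSE)
    window <- range(agg$period)
  }
  grid <- tidyr::expand_grid(
    practice_id = sort(unique(agg$practice_id)),
    period = period_seq(window[1], window[2])
  )
  panel <- grid |>
    dplyr::left_join(agg, by = c("practice_id", "period")) |>
    dplyr::mutate(dplyr::across(
      c("focal_items", "class_items", "total_items"),
      ~ tidyr::replace_na(.x, 0)
    )) |>
    dplyr::arrange(.data$practice_id, .data$period)
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  stopifnot(all(c("practice_id", "period", "focal_items", "class_items",
                  "total_items") %in% names(panel)))
  with(panel, {
    if (any(focal_items > class_items | class_items > total_items | focal_items < 0)) {
      stop("count invariant violated: need 0 <= focal <= class <= total",
           call. = FALSE)
    }
  })
  invisible(panel)
}

#' Write a practice-month panel back to the prescribing CSV dialect
#'
#' Emits up to three BNF product rows per practice-month (the focal product,
#' the rest of the class, and everything else) so that reading the file back
#' with [read_prescribing()] reproduces the counts exactly.
#'
#' @param panel a practice-month tibble as returned by [read_prescribing()].
#' @param path output CSV path.
#' @inheritParams read_prescribing
#' @return `path`, invisibly.
#' @export
write_prescribing <- function(panel, path, focal_code = "0704020AE",
                              class_code = "070402") {
  validate_panel(panel)
  pad <- function(code) {
    paste0(code, strrep("A", max(0, 15 - nchar(code))))
  }
  # class row must extend class_code without matching focal_code
  class_other <- pad(paste0(class_code, "0N0"))
  stopifnot(!startsWith(class_other, focal_code))
  out <- dplyr::bind_rows(
    dplyr::transmute(panel, PRACTICE = .data$practice_id, PERIOD = .data$period,
                     BNF_CODE = pad(focal_code), BNF_NAME = "FOCAL DRUG",
                     ITEMS = .data$focal_items),
    dplyr::transmute(panel, PRACTICE = .data$practice_id, PERIOD = .data$period,
                     BNF_CODE = class_other, BNF_NAME = "OTHER CLASS DRUG",
                     ITEMS = .data$class_items - .data$focal_items),
    dplyr::transmute(panel, PRACTICE = .data$practice_id, PERIOD = .data$period,
                     BNF_CODE = "0101010A0AAAAAA", BNF_NAME = "OTHER ITEM",
                     ITEMS = .data$total_items - .data$class_items)
  ) |>
    dplyr::arrange(.data$PRACTICE, .data$PERIOD, .data$BNF_CODE)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read or write a practice characteristics table
#'
#' One row per practice with the baseline workforce, registered-patient,
#' quality-indicator and deprivation fields used in exclusion rules and the
#' predictor model. Percentages must lie in `[0, 100]` and `imd_decile` in
#' `1..10`.
#'
#' @param path CSV path.
#' @return a tibble of practice profiles.
#' @export
read_profiles <- function(path) {
  prof <- readr::read_csv(
    path,
    col_types = readr::cols(
      practice_id = readr::col_character(),
      has_registrar = readr::col_logical(),
      imd_decile = readr::col_integer(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  validate_profiles(prof)
  prof
}

#' @rdname read_profiles
#' @param profiles a profiles tibble.
#' @export
write_profiles <- function(profiles, path) {
  validate_profiles(profiles)
  readr::write_csv(profiles, path, progress = FALSE)
  invisible(path)
}

profile_pct_fields <- c("pct_patients_65plus", "pct_patients_female",
                        "pct_gp_female", "pct_gp_45plus", "qof_overall_pct",
                        "hypertension_prevalence", "dementia_prevalence")

validate_profiles <- function(profiles) {
  need <- c("practice_id", "list_size", "gp_fte", "has_registrar",
            "imd_decile", profile_pct_fields)
  miss <- setdiff(need, names(profiles))
  if (length(miss)) {
    stop("profiles lack columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  for (f in profile_pct_fields) {
    v <- profiles[[f]]
    if (any(v < 0 | v > 100, na.rm = TRUE)) {
      stop("profile field `", f, "` outside [0, 100]", call. = FALSE)
    }
  }
  if (any(profiles$imd_decile < 1 | profiles$imd_decile > 10, na.rm = TRUE)) {
    stop("imd_decile outside 1..10", call. = FALSE)
  }
  if (any(profiles$list_size < 0, na.rm = TRUE)) {
    stop("negative list_size", call. = FALSE)
  }
  invisible(profiles)
}

#' Apply practice exclusion rules
#'
#' Removes atypical practices before analysis: very small lists, implausible
#' list-per-GP ratios, and practices contributing too few prescriptions in
#' the period surrounding the safety communication. A practice is excluded if
#' any of the following hold, and the report records the first rule that
#' fired:
#'
#' * `min_list`: `list_size < min_list` (default < 750 registered patients);
#' * `per_fte_undefined`: `gp_fte <= 0` with a non-zero list;
#' * `min_per_fte`: `list_size / gp_fte < min_per_fte` (default < 500);
#' * `max_per_fte`: `list_size / gp_fte > max_per_fte` (default > 5000);
#' * `min_items`: fewer than `min_items` prescription items in any single
#'   month of the window around `dhpc_month` (default the 13 months either
#'   side, i.e. August 2014 to October 2016 for a September 2015
#'   communication).
#'
#' Per-FTE boundaries are strict: practices exactly at 500 or 5000 patients
#' per FTE are retained. The `min_items` rule counts `total_items` by
#' default; set `items_basis = "class"` to count class items instead.
#'
#' @param panel practice-month tibble (see [read_prescribing()]).
#' @param profiles practice profiles tibble; every panel practice must appear.
#' @param dhpc_month `YYYYMM` month the safety communication was issued.
#' @param min_list,min_per_fte,max_per_fte,min_items rule thresholds.
#' @param items_basis count basis for the `min_items` rule.
#' @param window_months months on each side of `dhpc_month` (inclusive of the
#'   communication month itself) scanned by the `min_items` rule.
#' @return a list with `panel` (the filtered panel) and `report`, a tibble
#'   with one row per excluded practice (`practice_id`, `rule`, `value`).
#'   Every input practice is either retained or appears exactly once in the
#'   report, and re-applying the filter removes nothing further.
#' @export
apply_exclusions <- function(panel, profiles, dhpc_month,
                             min_list = 750, min_per_fte = 500,
                             max_per_fte = 5000, min_items = 100,
                             items_basis = c("total", "class"),
                             window_months = 13) {
  items_basis <- match.arg(items_basis)
  validate_panel(panel)
  validate_profiles(profiles)
  d_idx <- month_index(dhpc_month)
  if (!dhpc_month %in% panel$period) {
    stop("`dhpc_month` not present in panel", call. = FALSE)
  }
  ids <- unique(panel$practice_id)
  missing_prof <- setdiff(ids, profiles$practice_id)
  if (length(missing_prof)) {
    stop("panel practices missing from profiles: ",
         paste(utils::head(missing_prof, 5), collapse = ", "), call. = FALSE)
  }
  prof <- profiles[match(ids, profiles$practice_id), ]

  items_col <- if (items_basis == "total") "total_items" else "class_items"
  win <- panel |>
    dplyr::filter(abs(month_index(.data$period) - d_idx) <= window_months) |>
    dplyr::group_by(.data$practice_id) |>
    dplyr::summarise(min_monthly = min(.data[[items_col]]), .groups = "drop")
  min_monthly <- win$min_monthly[match(ids, win$practice_id)]

  rule <- rep(NA_character_, length(ids))
  value <- rep(NA_real_, length(ids))
  per_fte <- ifelse(prof$gp_fte > 0, prof$list_size / prof$gp_fte, NA_real_)

  hit <- function(cond, r, v) {
    sel <- is.na(rule) & !is.na(cond) & cond
    rule[sel] <<- r
    value[sel] <<- v[sel]
  }
  hit(prof$list_size < min_list, "min_list", prof$list_size)
  hit(prof$gp_fte <= 0 & prof$list_size > 0, "per_fte_undefined", prof$gp_fte)
  hit(per_fte < min_per_fte, "min_per_fte", per_fte)
  hit(per_fte > max_per_fte, "max_per_fte", per_fte)
  hit(!is.na(min_monthly) & min_monthly < min_items, "min_items", min_monthly)

  report <- tibble::tibble(practice_id = ids, rule = rule, value = value) |>
    dplyr::filter(!is.na(.data$rule))
  list(
    panel = dplyr::filter(panel, !.data$practice_id %in% report$practice_id),
    report = report
  )
}

#' Compute the focal drug's percentage share of its class
#'
#' Adds `share_pct = 100 * focal_items / class_items` to a practice-month
#' panel. Months with no class prescribing have an undefined share (`NA`),
#' not zero: a ratio with a zero denominator carries no information, and such
#' rows are excluded from downstream model and variation computations. The
#' number of undefined rows is attached as attribute `n_undefined`.
#'
#' @param panel practice-month tibble.
#' @return the panel with a `share_pct` column (a "share panel").
#' @export
compute_share <- function(panel) {
  validate_panel(panel)
  out <- dplyr::mutate(
    panel,
    share_pct = dplyr::if_else(.data$class_items > 0,
                               100 * .data$focal_items / .data$class_items,
                               NA_real_)
  )
  attr(out, "n_undefined") <- sum(is.na(out$share_pct))
  out
}

#' Summarise prescribing in one month
#'
#' @param share_panel a share panel from [compute_share()].
#' @param month `YYYYMM` period to summarise.
#' @return a one-row tibble: percentage of practices with any focal
#'   prescribing, mean/SD/median/IQR of the defined shares, and mean class
#'   and focal item counts.
#' @export
summarise_month <- function(share_panel, month) {
  rows <- dplyr::filter(share_panel, .data$period == month)
  if (nrow(rows) == 0) stop("month ", month, " absent from panel", call. = FALSE)
  sh <- rows$share_pct[!is.na(rows$share_pct)]
  tibble::tibble(
    period = as.integer(month),
    n_practices = nrow(rows),
    pct_practices_prescribing = 100 * mean(rows$focal_items > 0),
    mean_share = mean(sh),
    sd_share = stats::sd(sh),
    median_share = stats::median(sh),
    iqr_share = stats::IQR(sh, type = 7),
    mean_class_items = mean(rows$class_items),
    mean_focal_items = mean(rows$focal_items)
  )
}
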