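test_that("SCV truncates to zero when all practices sit at the pooled share", {
  sp <- manual_share_panel(c("A", "B", "C", "D"), 201509, rep(10, 4), 50L)
  res <- scv_month(sp, 201509, trim = c(0, 100))
  expect_equal(res$scv, 0)
  expect_lt(res$scv_raw, 0)
  expect_equal(res$band, "low")
})

test_that("SCV equals the hand-computed formula value", {
  panel <- tibble::tibble(
    practice_id = c("A", "B", "C", "D"), period = 201509L,
    focal_items = c(2L, 18L, 10L, 10L), class_items = rep(50L, 4),
    total_items = rep(5000L, 4)
  )
  sp <- compute_share(panel)
  res <- scv_month(sp, 201509, trim = c(0, 100))
  # pooled share 40/200 -> E_i = 10; sum((O-E)/E)^2 = 1.28, sum 1/E = 0.4
  # raw = 100/4 * (1.28 - 0.4) = 22
  expect_equal(res$scv, 22)
  expect_equal(res$k, 4)
  expect_equal(res$band, "very high")
})

test_that("SCV matches the brute-force oracle on random panels", {
  for (seed in 1:8) {
    sp <- random_month_panel(seed)
    res <- scv_month(sp, 201509)
    expect_equal(res$scv,
                 oracle_scv(sp$focal_items, sp$class_items),
                 tolerance = 1e-12)
  }
})

test_that("SCV is invariant to practice relabelling and respects trimming", {
  sp <- random_month_panel(42, n = 200)
  res <- scv_month(sp, 201509)
  perm <- sp[sample(nrow(sp)), ]
  expect_equal(scv_month(perm, 201509)$scv, res$scv)
  expect_gte(res$k / nrow(sp), 0.89)
  expect_lte(res$k, nrow(sp))
})

test_that("doubling counts cannot reduce SCV when the spread is held", {
  base <- tibble::tibble(
    practice_id = c("A", "B", "C", "D"), period = 201509L,
    focal_items = c(2L, 18L, 10L, 10L), class_items = rep(50L, 4),
    total_items = rep(5000L, 4)
  )
  doubled <- dplyr::mutate(base,
                           focal_items = focal_items * 2L,
                           class_items = class_items * 2L)
  s1 <- scv_month(compute_share(base), 201509, trim = c(0, 100))$scv
  s2 <- scv_month(compute_share(doubled), 201509, trim = c(0, 100))$scv
  expect_gte(s2, s1 - 1e-10)
})

test_that("exact rank-sum test reproduces enumeration results", {
  # identical samples: maximal p under mid-ranks
  expect_equal(exact_rank_sum_test(1:6, 1:6)$p.value, 1)
  # fully separated samples: only the two extreme assignments
  res <- exact_rank_sum_test(1:6, 7:12)
  expect_equal(res$p.value, 2 / choose(12, 6), tolerance = 1e-12)
  expect_equal(res$method, "exact")
  # random inputs, including ties, against full enumeration
  for (seed in 1:6) {
    set.seed(seed)
    x <- round(rnorm(6), 1)
    y <- round(rnorm(6, 0.5), 1)
    expect_equal(exact_rank_sum_test(x, y)$p.value, oracle_rank_sum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("exact rank-sum test keeps its nominal level under the null", {
  set.seed(99)
  p <- replicate(200, exact_rank_sum_test(rnorm(6), rnorm(6))$p.value)
  expect_lte(mean(p <= 0.05), 0.075)  # exact tests are level-valid
  expect_gte(min(p), 2 / choose(12, 6) - 1e-12)
})

test_that("pre/post SCV window comparison uses strict windows and exact p", {
  sim <- simulate_panel(sim_config(n_practices = 150, seed = 31))
  sp <- compute_share(sim$panel)
  res <- scv_window_compare(sp, 201509, w = 6)
  expect_equal(nrow(res$pre), 6)
  expect_equal(nrow(res$post), 6)
  expect_equal(res$pre$period, period_seq(201503, 201508))
  expect_equal(res$post$period, period_seq(201510, 201603))
  expect_false(201509 %in% c(res$pre$period, res$post$period))
  expect_equal(res$p_value,
               oracle_rank_sum_p(res$pre$scv, res$post$scv),
               tolerance = 1e-12)
  expect_error(scv_window_compare(sp, 201509, w = 20), "span")
})

test_that("standardized ratios satisfy their defining identities", {
  sp <- manual_share_panel(c("A", "B", "C"), 201509, c(5, 10, 15))
  rt <- standardized_ratios(sp, 201509)
  expect_equal(rt$ratio[rt$practice_id == "B"], 1)  # B sits at the pooled share

  sim <- simulate_panel(sim_config(n_practices = 120, seed = 14))
  sp2 <- compute_share(sim$panel)
  rt2 <- standardized_ratios(sp2) |>
    dplyr::left_join(dplyr::select(sp2, "practice_id", "period", "class_items"),
                     by = c("practice_id", "period"))
  wmean <- rt2 |>
    dplyr::filter(!is.na(ratio)) |>
    dplyr::group_by(period) |>
    dplyr::summarise(w = sum(class_items * ratio) / sum(class_items))
  expect_true(all(abs(wmean$w - 1) < 1e-12))

  # min/max agree with direct recomputation in one month
  one <- rt2[rt2$period == 201509 & !is.na(rt2$ratio), ]
  sub <- sp2[sp2$period == 201509 & !is.na(sp2$share_pct), ]
  pooled <- 100 * sum(sub$focal_items) / sum(sub$class_items)
  expect_equal(range(one$ratio), range(sub$share_pct / pooled))
})

test_that("rolling ratios are flat for constant series and match quantile oracle", {
  months <- period_seq(201501, 201512)
  sp <- manual_share_panel(rep(c("A", "B"), each = 12), rep(months, 2),
                           rep(c(8, 12), each = 12))
  roll <- rolling_ratio_distribution(sp, ref_month = 201509)
  expect_true(all(abs(roll$ratios$ratio - 1) < 1e-12))

  # single practice, shares 2..12 then a reference month at their mean
  sp1 <- manual_share_panel("A", period_seq(201501, 201507),
                            c(2, 4, 6, 8, 10, 12, 7), class_items = 1000L)
  r1 <- rolling_ratio_distribution(sp1, ref_month = 201507)
  at6 <- r1$ratios[r1$ratios$period == 201506, ]
  expect_equal(at6$ratio, 1, tolerance = 1e-9)

  sim <- simulate_panel(sim_config(n_practices = 80, seed = 19))
  sp2 <- compute_share(sim$panel)
  r2 <- rolling_ratio_distribution(sp2, 201509)
  m <- 201606L
  vals <- r2$ratios$ratio[r2$ratios$period == m & !is.na(r2$ratios$ratio)]
  pc <- r2$percentiles[r2$percentiles$period == m, ]
  probs <- c(1:9, seq(10, 90, 10), 91:99) / 100
  expect_equal(pc$prob, probs)
  expect_equal(pc$value, quantile(vals, probs, type = 7, names = FALSE))
})

test_that("high planted heterogeneity yields a very-high SCV band", {
  cfg <- sim_config(n_practices = 800, sigma_b = c(6, 0.08, 0.15, 0.02),
                    seed = 5)
  sp <- compute_share(simulate_panel(cfg)$panel)
  res <- scv_month(sp, 201509)
  expect_gt(res$scv, 10)
  expect_equal(res$band, "very high")
})
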