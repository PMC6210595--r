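test_that("prescribing rows aggregate by BNF prefix with zero-fill", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    PRACTICE = c("P1", "P1", "P1", "P2"),
    PERIOD = c(201509, 201509, 201510, 201509),
    BNF_CODE = c("0704020AEBBAAAA", "0704020N0AAAAAA", "0212000AAAAAAAA",
                 "0704020AEBBAAAB"),
    BNF_NAME = "x",
    ITEMS = c(5, 20, 7, 3)
  ), f)
  panel <- read_prescribing(f)
  p1sep <- dplyr::filter(panel, practice_id == "P1", period == 201509)
  expect_equal(p1sep$focal_items, 5)
  expect_equal(p1sep$class_items, 25)
  expect_equal(p1sep$total_items, 25)
  # missing practice-months inside the window are zero rows
  p2oct <- dplyr::filter(panel, practice_id == "P2", period == 201510)
  expect_equal(p2oct$total_items, 0)
  expect_equal(nrow(panel), 4)  # 2 practices x 2 months

  # no focal rows at all is still a valid panel
  panel0 <- read_prescribing(f, focal_code = "0704020ZZ")
  expect_true(all(panel0$focal_items == 0))
})

test_that("prescribing reader validates inputs", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    PRACTICE = "P1", PERIOD = 201513, BNF_CODE = "0704020AEBBAAAA",
    BNF_NAME = "x", ITEMS = 5
  ), f)
  expect_error(read_prescribing(f), "malformed period")
  readr::write_csv(tibble::tibble(
    PRACTICE = "P1", PERIOD = 201509, BNF_CODE = "0704020AEBBAAAA",
    BNF_NAME = "x", ITEMS = -5
  ), f)
  expect_error(read_prescribing(f), "negative ITEMS")
  expect_error(read_prescribing(f, focal_code = "0301", class_code = "070402"),
               "prefix")
})

test_that("aggregated counts equal independently computed sums", {
  set.seed(11)
  raw <- tidyr::expand_grid(
    PRACTICE = c("A", "B", "C"), PERIOD = c(201501, 201502),
    BNF_CODE = c("0704020AEAAAAAA", "0704020N0BBBBBB", "0501010C0AAAAAA")
  ) |>
    dplyr::mutate(BNF_NAME = "x", ITEMS = rpois(dplyr::n(), 30))
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(raw, f)
  panel <- read_prescribing(f)
  for (pr in c("A", "B", "C")) {
    for (mo in c(201501, 201502)) {
      sub <- raw[raw$PRACTICE == pr & raw$PERIOD == mo, ]
      row <- panel[panel$practice_id == pr & panel$period == mo, ]
      expect_equal(row$total_items, sum(sub$ITEMS))
      expect_equal(row$class_items,
                   sum(sub$ITEMS[startsWith(sub$BNF_CODE, "070402")]))
      expect_equal(row$focal_items,
                   sum(sub$ITEMS[startsWith(sub$BNF_CODE, "0704020AE")]))
    }
  }
})

test_that("panel and profile write/read round-trips are exact", {
  sim <- simulate_panel(sim_config(n_practices = 8, start = 201501,
                                   end = 201512, dhpc_month = 201506,
                                   seed = 4))
  d <- withr::local_tempdir()
  write_prescribing(sim$panel, file.path(d, "rx.csv"))
  back <- read_prescribing(file.path(d, "rx.csv"))
  expect_equal(as.data.frame(back), as.data.frame(sim$panel))
  write_profiles(sim$profiles, file.path(d, "prof.csv"))
  prof <- read_profiles(file.path(d, "prof.csv"))
  expect_equal(as.data.frame(prof), as.data.frame(sim$profiles))
})

test_that("exclusion rules fire as specified, with boundaries retained", {
  ids <- sprintf("E%02d", 1:9)
  panel <- flat_panel(ids)
  profiles <- ok_profile(ids)
  profiles$list_size[2] <- 700                      # min_list
  profiles$list_size[3] <- 750; profiles$gp_fte[3] <- 1.5   # boundary: keep
  profiles$list_size[4] <- 2000; profiles$gp_fte[4] <- 5    # 400/FTE
  profiles$list_size[5] <- 2500; profiles$gp_fte[5] <- 5    # exactly 500: keep
  profiles$list_size[6] <- 6000; profiles$gp_fte[6] <- 1    # 6000/FTE
  profiles$gp_fte[7] <- 0                           # per-FTE undefined
  # low month inside the +/-13 month window (Aug 2014)
  low8 <- panel$practice_id == ids[8] & panel$period == 201408
  panel$total_items[low8] <- 99L
  panel$class_items[low8] <- 50L
  panel$focal_items[low8] <- 5L
  # low month outside the window (Jul 2014): retained
  low9 <- panel$practice_id == ids[9] & panel$period == 201407
  panel$total_items[low9] <- 99L
  panel$class_items[low9] <- 50L
  panel$focal_items[low9] <- 5L

  res <- apply_exclusions(panel, profiles, 201509)
  expect_setequal(res$report$practice_id, ids[c(2, 4, 6, 7, 8)])
  rules <- setNames(res$report$rule, res$report$practice_id)
  expect_equal(unname(rules[ids[c(2, 4, 6, 7, 8)]]),
               c("min_list", "min_per_fte", "max_per_fte",
                 "per_fte_undefined", "min_items"))
  expect_setequal(unique(res$panel$practice_id), ids[c(1, 3, 5, 9)])

  # first-triggered-rule reporting: a practice violating several rules
  # appears once, under the earliest rule
  profiles2 <- profiles
  profiles2$list_size[1] <- 600; profiles2$gp_fte[1] <- 0
  res2 <- apply_exclusions(panel, profiles2, 201509)
  expect_equal(sum(res2$report$practice_id == ids[1]), 1)
  expect_equal(res2$report$rule[res2$report$practice_id == ids[1]], "min_list")

  # partition: every practice retained or reported exactly once
  expect_setequal(c(unique(res2$panel$practice_id), res2$report$practice_id), ids)

  # idempotence
  res3 <- apply_exclusions(res$panel, profiles, 201509)
  expect_equal(nrow(res3$report), 0)
  expect_equal(as.data.frame(res3$panel), as.data.frame(res$panel))
})

test_that("min-items rule can count class items instead of all items", {
  ids <- c("C1", "C2")
  panel <- flat_panel(ids, class_items = 150L)
  panel$class_items[panel$practice_id == "C1" & panel$period == 201601] <- 99L
  panel$focal_items[panel$practice_id == "C1" & panel$period == 201601] <- 5L
  profiles <- ok_profile(ids)
  res_total <- apply_exclusions(panel, profiles, 201509)
  expect_equal(nrow(res_total$report), 0)
  res_class <- apply_exclusions(panel, profiles, 201509, items_basis = "class")
  expect_equal(res_class$report$practice_id, "C1")
})

test_that("share construction handles zero numerators and denominators", {
  panel <- tibble::tibble(
    practice_id = c("S1", "S2", "S3"), period = 201509L,
    focal_items = c(7L, 0L, 0L), class_items = c(100L, 40L, 0L),
    total_items = c(5000L, 5000L, 5000L)
  )
  sp <- compute_share(panel)
  expect_equal(sp$share_pct, c(7, 0, NA))
  expect_equal(attr(sp, "n_undefined"), 1)
  expect_true(all(sp$share_pct >= 0 & sp$share_pct <= 100, na.rm = TRUE))
})

test_that("monthly summary matches direct computation", {
  sp <- manual_share_panel(c("A", "B"), 201509, c(10, 20))
  s <- summarise_month(sp, 201509)
  expect_equal(s$mean_share, 15)
  expect_equal(s$pct_practices_prescribing, 100)

  sp2 <- manual_share_panel(c("A", "B"), 201509, c(0, 20))
  expect_equal(summarise_month(sp2, 201509)$pct_practices_prescribing, 50)
  expect_error(summarise_month(sp2, 201601), "absent")

  # moments over a simulated month agree with direct recomputation
  sim <- simulate_panel(sim_config(n_practices = 200, seed = 9))
  sp3 <- compute_share(sim$panel)
  s3 <- summarise_month(sp3, 201509)
  sub <- sp3[sp3$period == 201509, ]
  expect_equal(s3$mean_share, mean(sub$share_pct, na.rm = TRUE))
  expect_equal(s3$sd_share, sd(sub$share_pct, na.rm = TRUE))
  expect_equal(s3$median_share, median(sub$share_pct, na.rm = TRUE))
  expect_equal(s3$pct_practices_prescribing, 100 * mean(sub$focal_items > 0))
})
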