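aml_heights_curve <- function() {
  fit <- km_curve(aml_maintained())
  # heights only, as read off a figure: raw observation times withheld
  step_curve(tidy(fit$curve)[, c("t", "S")], end_time = 161)
}

test_that("AML jumps and ratios match the worked values", {
  jr <- jumps_and_ratios(aml_heights_curve())
  expect_equal(round(jr$jump[1], 5), 0.09091)
  expect_equal(round(jr$jump[2], 5), 0.09091)
  expect_equal(round(jr$jump[3], 5), 0.10227)
  expect_equal(jr$ratio, 1 - 1 / c(11, 10, 8, 7, 5, 4, 2))
})

test_that("product-limit inversion recovers n from adjacent heights", {
  expect_equal(infer_n_km(1, 0.90909090909, 1), 11, tolerance = 1e-8)
  expect_equal(infer_n_km(1, 0.5, 1), 2)
  expect_error(infer_n_km(0.5, 0.5, 1), "no jump")

  sim <- simulate_study(60, hazard = 0.2, censoring = "uniform", seed = 9)
  fit <- km_curve(sim$ipd)
  jr <- jumps_and_ratios(fit$curve)
  n_hat <- infer_n_km(jr$S_prev, jr$S, fit$table$d)
  expect_equal(n_hat, fit$table$n, tolerance = 1e-9)
})

test_that("Nelson-Aalen inversion is exact by construction", {
  expect_equal(infer_n_na(0, 0.1, 1), 10)
  expect_equal(infer_n_na(0.2, 0.21, 2), 200)
  expect_error(infer_n_na(0.2, 0.2, 1), "increment")

  sim <- simulate_study(80, hazard = 0.15, censoring = "admin", seed = 13)
  fit <- na_curve(sim$ipd)
  jr <- jumps_and_ratios(fit$curve)
  n_hat <- infer_n_na(jr$S_prev, jr$S, fit$table$d)
  expect_equal(n_hat, fit$table$n, tolerance = 1e-9)
})

test_that("cumulative-incidence inversion matches its survival complement", {
  expect_equal(infer_n_ci(0, 0.1, 1), 10)
  expect_equal(infer_n_ci(0.5, 0.75, 1), 2)
  expect_error(infer_n_ci(0.3, 0.3, 1), "increase")

  sim <- simulate_study(70, hazard = 0.2, censoring = "uniform", seed = 17)
  fit <- ci_curve(sim$ipd)
  jr <- jumps_and_ratios(fit$curve)
  n_hat <- infer_n_ci(jr$S_prev, jr$S, fit$table$d)
  expect_equal(n_hat, fit$table$n, tolerance = 1e-9)
})

test_that("multiplicity detection repairs halved and thirded entries", {
  # oracle: product-limit heights from n0 = 50 with 2 tied deaths at the
  # third event time invert (under d = 1) to exactly these raw values
  # (the printed tail 47, 46 is not reachable from n3 = 48 with d3 = 2, so
  # the detector also flags the sequence as bookkeeping-inconsistent)
  out <- suppressWarnings(detect_multiplicities(c(50, 49, 24, 47, 46)))
  expect_equal(out$d, c(1L, 1L, 2L, 1L, 1L))
  expect_equal(out$n, c(50, 49, 48, 47, 46))

  # a bookkeeping-consistent tied sequence raises no flags: product-limit
  # counts from n0 = 50 with the 2 tied deaths at the third event time
  expect_no_warning(ok <- detect_multiplicities(c(50, 49, 24, 46, 45)))
  expect_equal(ok$d, c(1L, 1L, 2L, 1L, 1L))
  expect_equal(ok$n, c(50, 49, 48, 46, 45))

  monotone <- detect_multiplicities(c(10, 9, 8, 7, 6))
  expect_equal(monotone$d, rep(1L, 5))
  expect_equal(monotone$n, c(10, 9, 8, 7, 6))

  third <- suppressWarnings(detect_multiplicities(c(30, 29, 28 / 3, 27, 26)))
  expect_equal(third$d[3], 3L)
  expect_equal(third$n[3], 28)
})

test_that("AML risk-set table is recovered from heights alone", {
  tab <- reconstruct_risk_table(aml_heights_curve())
  expect_equal(tab$n, c(11, 10, 8, 7, 5, 4, 2))
  expect_equal(tab$d, rep(1L, 7))
  expect_equal(tab$c, c(0L, 1L, 0L, 1L, 0L, 1L, 1L))
  # bookkeeping identity
  expect_equal(tab$n[-1], (tab$n - tab$d - tab$c)[-7])
})

test_that("equal jumps of 1/n0 imply no interior censoring", {
  ipd <- tibble::tibble(time = 1:8, status = 1)
  tab <- reconstruct_risk_table(km_curve(ipd)$curve)
  expect_equal(tab$n, 8:1)
  expect_equal(tab$c, rep(0L, 8))
})

test_that("reported at-risk anchors override the inferred values", {
  curve <- aml_heights_curve()
  tab <- reconstruct_risk_table(curve,
                                reported_at_risk = data.frame(t = 9, n = 11))
  expect_equal(tab$n[1], 11L)
})

test_that("jumps plus visible marks lower-bound the sample size", {
  p <- recover_pipeline(km_curve(aml_maintained()), censor_style = "tick")
  expect_equal(infer_n0_lower_bound(p$curve, p$marks), 10L)
  expect_equal(infer_n0_lower_bound(p$curve), 7L)
  # the full reconstruction finds one more (the unmarked "t+" censoring)
  expect_gte(attr(p$table, "n0"), 10L)
  expect_equal(attr(p$table, "n0"), 11L)
})

test_that("individual records are rebuilt with marked and t+ censoring", {
  p <- recover_pipeline(km_curve(aml_maintained()), censor_style = "tick")
  ipd <- reconstruct_ipd(p$table, marks = p$marks)
  expect_equal(nrow(ipd), 11L)
  expect_equal(sum(ipd$status == 1), 7L)
  expect_equal(sum(ipd$status == 0), 4L)
  # the unmarked censoring lands immediately after its event time (times
  # carry the figure's 3-decimal coordinate rounding)
  t_plus <- ipd$time[ipd$status == 0 & ipd$time < 20]
  expect_equal(t_plus, 13, tolerance = 1e-3)
  expect_gt(t_plus, p$table$t[2])
  # marked censorings land on their marks
  expect_equal(sort(ipd$time[ipd$status == 0])[-1], c(28, 45, 161),
               tolerance = 1e-3)
})

test_that("tables without censoring rebuild as pure event records", {
  ipd <- tibble::tibble(time = c(1, 2, 2, 3), status = 1)
  rebuilt <- reconstruct_ipd(risk_table_from_ipd(ipd))
  expect_equal(rebuilt$time, ipd$time)
  expect_equal(rebuilt$status, rep(1, 4))
})

test_that("KM of the reconstructed records reproduces the input curve", {
  sim <- simulate_study(45, hazard = 0.2, censoring = "uniform", seed = 23)
  p <- recover_pipeline(km_curve(sim$ipd))
  ipd2 <- reconstruct_ipd(p$table, marks = p$marks)
  refit <- km_curve(ipd2)
  expect_equal(refit$curve$S, km_curve(sim$ipd)$curve$S, tolerance = 1e-9)
})

test_that("person-time integrates exposure over half-open intervals", {
  two <- tibble::tibble(time = c(1, 2), status = c(1, 0))
  pt <- person_time(two, boundaries = c(0, 2))
  expect_equal(pt$events, 1L)
  expect_equal(pt$person_time, 3)

  # oracle: brute-force per-subject accumulation on the AML records
  ipd <- aml_maintained()
  grid <- seq(0, 168, by = 12)
  pt <- person_time(ipd, boundaries = grid)
  brute_pt <- vapply(seq_len(length(grid) - 1), function(i) {
    sum(vapply(ipd$time, function(ti) {
      max(0, min(ti, grid[i + 1]) - grid[i])
    }, double(1)))
  }, double(1))
  brute_ev <- vapply(seq_len(length(grid) - 1), function(i) {
    sum(ipd$status == 1 & ipd$time >= grid[i] & ipd$time < grid[i + 1])
  }, double(1))
  expect_equal(pt$person_time, brute_pt)
  expect_equal(pt$events, as.integer(brute_ev))
  expect_equal(sum(pt$person_time), sum(ipd$time))
})

test_that("validation reports deviations and localises perturbations", {
  curve <- aml_heights_curve()
  tab <- reconstruct_risk_table(curve)
  rep0 <- validate_reconstruction(curve, tab)
  expect_true(rep0$pass)
  expect_lt(rep0$max_deviation, 1e-9)

  tab2 <- tab
  tab2$n[3] <- tab2$n[3] + 1L
  rep1 <- validate_reconstruction(curve, tab2)
  expect_false(rep1$pass)
  expect_equal(which.max(rep1$deviation_by_time$deviation >= 1e-6), 3L)

  empty <- validate_reconstruction(
    step_curve(tibble::tibble(t = 0, S = 1)),
    risk_table_from_ipd(tibble::tibble(time = 1, status = 0)))
  expect_true(empty$pass)
})

test_that("negative implied censoring aborts with diagnostics", {
  # heights rising too slowly for their own good: n sequence that rebounds
  curve <- step_curve(tibble::tibble(t = c(0, 1, 2),
                                     S = c(1, 0.5, 0.45)))
  # jump 1: n = 2; jump 2: n = 10 > 2 - 1: impossible without repair info
  expect_error(suppressWarnings(reconstruct_risk_table(curve)),
               class = "kmrecover_negative_censoring")
})
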