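test_that("MAE is the masked mean absolute error relative to prescription", {
  d <- array(3000, c(4, 4, 4))
  mask <- array(1, c(4, 4, 4))
  expect_equal(mae_percent(d, d, mask, 5400), 0)
  expect_equal(mae_percent(d, d + 54, mask, 5400), 1.0)
  # three-voxel mask with |diffs| = 0, 54, 108 cGy
  m3 <- array(0, c(4, 4, 4)); m3[1:3, 1, 1] <- 1
  pred <- d; pred[2, 1, 1] <- d[2, 1, 1] + 54; pred[3, 1, 1] <- d[3, 1, 1] - 108
  expect_equal(mae_percent(d, pred, m3, 5400), 1.0)
  expect_error(mae_percent(d, d, array(0, c(4, 4, 4)), 5400), "empty")
})

test_that("cumulative DVH reproduces counting oracles and is monotone", {
  mask <- array(1, c(4, 4, 4))
  u <- array(5400, c(4, 4, 4))
  dvh <- cumulative_dvh(u, mask)
  expect_equal(dvh$volume_pct[dvh$dose == 0], 100)
  expect_equal(dvh$volume_pct[dvh$dose == 5400], 100)
  expect_equal(dvh$volume_pct[dvh$dose == 5410], 0)
  half <- u; half[1:2, , ] <- 0
  dvh2 <- cumulative_dvh(half, mask)
  expect_equal(dvh2$volume_pct[dvh2$dose == 3000], 50)
  set.seed(8)
  for (r in 1:5) {
    dvh3 <- cumulative_dvh(rand_vol(6), array(1, c(6, 6, 6)))
    expect_true(all(diff(dvh3$volume_pct) <= 0))
    expect_equal(dvh3$volume_pct[1], 100)
    expect_equal(dvh3$volume_pct[nrow(dvh3)], 0)
  }
})

test_that("Dp and Vd queries follow the descending-rank convention", {
  mask <- array(0, c(10, 1, 1)); mask[, 1, 1] <- 1
  d <- array(0, c(10, 1, 1)); d[, 1, 1] <- seq(100, 1000, by = 100)
  expect_equal(dvh_query(d, mask, "D", 95), 100)
  expect_equal(dvh_query(d, mask, "D", 50), 600)
  expect_equal(dvh_query(d, mask, "V", 550), 50)
  u <- array(5400, c(3, 3, 3)); mu <- array(1, c(3, 3, 3))
  for (p in c(2, 50, 98)) expect_equal(dvh_query(u, mu, "D", p), 5400)
  expect_equal(dvh_query(u, mu, "V", 4000), 100)
})

test_that("Dp/Vd duality holds on random dose fields", {
  set.seed(10)
  for (r in 1:100) {
    d <- rand_vol(5)
    mask <- array(1, c(5, 5, 5))
    p <- runif(1, 1, 99)
    dp <- dvh_query(d, mask, "D", p)
    expect_gte(dvh_query(d, mask, "V", dp), p)
    for (q in quantile(d, c(0.1, 0.5, 0.9)))
      expect_equal(dvh_query(d, mask, "V", q) >= p, q <= dp)
  }
})

test_that("HI matches its closed form and is scale invariant", {
  expect_equal(homogeneity_index(list(D2 = 5960, D98 = 5420, D50 = 5700)),
               (5960 - 5420) / 5700)
  expect_equal(homogeneity_index(list(D2 = 5400, D98 = 5400, D50 = 5400)), 0)
  expect_equal(homogeneity_index(list(D2 = 2 * 5960, D98 = 2 * 5420, D50 = 2 * 5700)),
               homogeneity_index(list(D2 = 5960, D98 = 5420, D50 = 5700)),
               tolerance = 1e-12)
  expect_error(homogeneity_index(list(D2 = 1, D98 = 1, D50 = 0)), "D50")
})

test_that("CI counts target and prescription-isodose volumes exactly", {
  dim3 <- c(8, 8, 8)
  ptv <- array(0, dim3); ptv[2:5, 2:5, 2:5] <- 1
  dose <- array(0, dim3); dose[ptv == 1] <- 5400
  expect_equal(conformity_index(ptv, dose, 5400), 1)
  off <- array(0, dim3); off[6:8, 6:8, 6:8] <- 5400
  expect_equal(conformity_index(ptv, off, 5400), 0)
  # V_T = 100, V_P = 120, V_TP = 90 -> 90^2/(100*120)
  ptv2 <- array(0, c(10, 10, 10)); ptv2[1:100] <- 1
  dose2 <- array(0, c(10, 10, 10)); dose2[11:130] <- 5400
  expect_equal(sum(ptv2), 100); expect_equal(sum(dose2 >= 5400), 120)
  expect_equal(conformity_index(ptv2, dose2, 5400), 90^2 / (100 * 120))
  expect_error(conformity_index(array(0, dim3), dose, 5400), "empty")
})

test_that("isodose Dice follows the set-count oracle", {
  d <- array(0, c(10, 10, 10))
  a <- d; a[1:80] <- 5400
  b <- d; b[31:90] <- 5400
  expect_equal(isodose_dsc(a, b, 100, prescription = 5400), 2 * 50 / (80 + 60))
  expect_equal(isodose_dsc(a, a, 100, prescription = 5400), 1)
  disj <- d; disj[101:160] <- 5400
  expect_equal(isodose_dsc(a, disj, 100, prescription = 5400), 0)
  expect_warning(v <- isodose_dsc(d, d, 100, prescription = 5400), "empty")
  expect_equal(v, 1)
  # self-comparison is 1 at every level
  cs <- tiny_case()
  for (lv in c(20, 50, 90))
    expect_equal(isodose_dsc(cs$dose, cs$dose, lv), 1)
})

test_that("gamma analysis reproduces flat-field closed forms", {
  rx <- 5400
  ref <- dose_distribution(volume_grid(array(rx / 2, c(8, 8, 8)),
                                       spacing = rep(3.5, 3)), rx)
  same <- gamma_passing_rate(ref, ref)
  expect_equal(same$rates$gpr[same$rates$structure == "global"], 100)
  expect_true(all(same$gamma == 0, na.rm = TRUE))
  # +2% of Rx on a flat field: gamma = 2/3 everywhere, all pass
  up2 <- array(rx / 2 + 0.02 * rx, c(8, 8, 8))
  g2 <- gamma_passing_rate(ref, up2)
  expect_equal(unique(stats::na.omit(as.numeric(g2$gamma))), 2 / 3,
               tolerance = 1e-9)
  expect_equal(g2$rates$gpr[1], 100)
  # +6%: gamma = 2, none pass
  up6 <- array(rx / 2 + 0.06 * rx, c(8, 8, 8))
  g6 <- gamma_passing_rate(ref, up6)
  expect_equal(unique(stats::na.omit(as.numeric(g6$gamma))), 2,
               tolerance = 1e-9)
  expect_equal(g6$rates$gpr[1], 0)
  # flat-field symmetry under ref/eval swap
  ref2 <- dose_distribution(volume_grid(up2, spacing = rep(3.5, 3)), rx)
  g2r <- gamma_passing_rate(ref2, ref$grid$values)
  expect_equal(unique(stats::na.omit(as.numeric(g2r$gamma))), 2 / 3,
               tolerance = 1e-9)
  # voxels below the 10% threshold are excluded
  low <- ref; low$grid$values[1:4, , ] <- 0.05 * rx
  gl <- gamma_passing_rate(low, low$grid$values)
  expect_equal(gl$rates$n_eval[1], 4 * 8 * 8)
  expect_error(gamma_passing_rate(array(1, c(4, 4, 4)), array(1, c(4, 4, 4)),
                                  prescription = rx),
               "spacing")
})

test_that("gamma never increases when criteria are loosened", {
  set.seed(33)
  cs <- clean_case()
  pred <- cs$dose$grid$values * 0.97 + 40
  # dose-difference criterion (same sampling grid)
  tight <- gamma_passing_rate(cs$dose, pred, dd_pct = 2)
  loose <- gamma_passing_rate(cs$dose, pred, dd_pct = 3)
  sel <- !is.na(tight$gamma)
  expect_true(all(loose$gamma[sel] <= tight$gamma[sel] + 1e-9))
  expect_gte(loose$rates$gpr[1], tight$rates$gpr[1])
  # DTA criterion, compared on a common interpolation grid
  t2 <- gamma_passing_rate(cs$dose, pred, dta_mm = 2, step_mm = 0.3)
  l2 <- gamma_passing_rate(cs$dose, pred, dta_mm = 3, step_mm = 0.3)
  expect_true(all(l2$gamma[sel] <= t2$gamma[sel] + 1e-9))
  expect_gte(l2$rates$gpr[1], t2$rates$gpr[1])
})

test_that("difference histograms report bias, sd and conserve counts", {
  cs <- tiny_case()
  gt <- cs$dose
  mask <- cs$structures$masks$body
  h0 <- difference_histogram(gt, gt, mask)
  expect_equal(attr(h0, "bias"), 0)
  expect_equal(sum(h0$count), sum(mask))
  shifted <- gt$grid$values + 100
  h1 <- difference_histogram(gt, shifted, mask)
  expect_equal(attr(h1, "bias"), 100, tolerance = 1e-9)
  expect_equal(sum(h1$count), sum(mask))
})

test_that("the paired t-test matches the textbook formula and flags degeneracy", {
  r <- paired_ttest(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(r$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-9)
  # constant shift with tiny noise: overwhelming evidence
  set.seed(12)
  b <- rnorm(10)
  r2 <- paired_ttest(b + 1 + rnorm(10, sd = 1e-6), b)
  expect_lt(r2$p, 1e-6)
  # alternating +/- c differences: t = 0, p = 1
  r3 <- paired_ttest(c(1, -1, 1, -1), c(0, 0, 0, 0))
  expect_equal(r3$t, 0)
  expect_equal(r3$p, 1)
  # zero-variance differences are degenerate, no p emitted
  r4 <- paired_ttest(c(2, 3, 4), c(1, 2, 3))
  expect_true(r4$degenerate)
  expect_true(is.na(r4$p))
  expect_error(paired_ttest(1:3, 1:4), "equal length")
})

test_that("a self-comparison report is ideal on every metric", {
  cs <- tiny_case()
  rep <- evaluate_case(cs$dose, cs$dose, cs$structures)
  expect_true(all(rep$mae$mae_pct == 0))
  expect_true(all(rep$dsc$dsc == 1))
  expect_true(all(rep$gamma_rates$gpr == 100, na.rm = TRUE))
  expect_true(all(rep$indices$diff == 0))
  expect_equal(attr(rep$histogram, "bias"), 0)
})

test_that("the evaluation report covers the full dosimetric schema", {
  cs <- tiny_case()
  pred <- dose_distribution(
    volume_grid(pmax(cs$dose$grid$values * 0.98 + 20, 0), cs$dose$grid$spacing),
    cs$dose$prescription)
  rep <- evaluate_case(cs$dose, pred, cs$structures)
  ptv_metrics <- rep$indices$metric[rep$indices$structure == "ptv"]
  expect_true(all(c("D99", "D98", "D95", "D50", "D2", "Dmax", "Dmean",
                    "HI", "CI") %in% ptv_metrics))
  for (oar in c("bladder", "rectum"))
    expect_true(all(c("Dmax", "Dmean", "V40") %in%
                    rep$indices$metric[rep$indices$structure == oar]))
  for (oar in c("femur_head_l", "femur_head_r"))
    expect_true(all(c("Dmax", "Dmean") %in%
                    rep$indices$metric[rep$indices$structure == oar]))
  expect_setequal(rep$mae$structure,
                  c("body", "ptv", "bladder", "rectum", "femur_head_l",
                    "femur_head_r"))
  expect_true("global" %in% rep$gamma_rates$structure)
  # ordering chain of the PTV dose indices, both columns
  for (col in c("clinical", "predicted")) {
    v <- rep$indices[rep$indices$structure == "ptv", ]
    get <- function(m) v[[col]][v$metric == m]
    expect_true(get("D99") <= get("D98") && get("D98") <= get("D95") &&
                get("D95") <= get("D50") && get("D50") <= get("D2") &&
                get("D2") <= get("Dmax"))
  }
  # CI and DSC stay in [0, 1]
  ci <- rep$indices[rep$indices$structure == "ptv" & rep$indices$metric == "CI", ]
  expect_true(all(c(ci$clinical, ci$predicted) >= 0 & c(ci$clinical, ci$predicted) <= 1))
  expect_true(all(rep$dsc$dsc >= 0 & rep$dsc$dsc <= 1))
  # indices agree with independent recomputation from the raw arrays
  ptv <- cs$structures$masks$ptv
  x <- sort(pred$grid$values[ptv == 1], decreasing = TRUE)
  d50 <- x[ceiling(0.5 * length(x))]
  v <- rep$indices
  expect_equal(v$predicted[v$structure == "ptv" & v$metric == "D50"], d50)
  expect_equal(v$predicted[v$structure == "ptv" & v$metric == "Dmean"], mean(x))
  # report writing produces the CSV/JSON artifacts
  dir <- tempfile()
  write_eval_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("indices.csv", "mae.csv",
                                               "dsc.csv", "gamma.csv",
                                               "dvh.csv", "report.json")))))
  # tidy/glance/autoplot interfaces
  expect_s3_class(tidy(rep), "tbl_df")
  expect_s3_class(glance(rep), "tbl_df")
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
})
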