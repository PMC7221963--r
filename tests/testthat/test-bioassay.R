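test_that("percent inhibition is the fractional signal reduction", {
  expect_equal(percent_inhibition(0.70, 0.70), 0)
  expect_equal(percent_inhibition(0.35, 0.70), 50)
  expect_equal(percent_inhibition(0.00, 0.70), 100)
  expect_error(percent_inhibition(0.1, 0), "positive")
})

test_that("ID50 interpolation is exact on log-symmetric responses", {
  # response hits 50% exactly at a grid dose
  dr <- dose_response("s", "DPPH", c(1.56, 3.125, 6.25), c(30, 50, 70))
  est <- estimate_id50(dr)
  expect_equal(est$value, 3.125)
  expect_true(est$bracketed)
  # responses 25/75 at doses 1/10: log-linear crossing at 10^0.5
  dr2 <- dose_response("s", "DPPH", c(1, 10), c(25, 75))
  expect_equal(estimate_id50(dr2)$value, 10^0.5, tolerance = 1e-12)
  # 50% never reached: flagged extrapolation
  dr3 <- dose_response("s", "ABTS", c(1, 2, 4), c(10, 20, 30))
  est3 <- estimate_id50(dr3)
  expect_false(est3$bracketed)
  expect_gt(est3$value, 4)
  expect_error(estimate_id50(dose_response("s", "DPPH", 5, 50)), "2 dose")
})

test_that("non-monotone responses are isotonically cleaned or rejected", {
  # small inversion (within 5% of range) is projected away
  dr <- dose_response("s", "DPPH", c(1, 2, 4, 8, 16),
                      c(20, 41, 40, 60, 80))
  expect_true(is.finite(estimate_id50(dr)$value))
  # gross non-monotonicity is an error
  dr_bad <- dose_response("s", "DPPH", c(1, 2, 4, 8, 16),
                          c(20, 70, 30, 60, 80))
  expect_error(estimate_id50(dr_bad), "non-monotone")
})

test_that("the 4PL alternative recovers a clean Hill curve", {
  d <- c(0.78, 1.56, 3.125, 6.25, 12.5)
  y <- 100 * d^1.5 / (d^1.5 + 3^1.5)
  dr <- dose_response("s", "DPPH", d, y)
  est <- estimate_id50(dr, method = "4pl")
  expect_equal(est$value, 3, tolerance = 0.02)
})

test_that("TEAC is the Trolox/sample ID50 ratio and multiplies transitively", {
  expect_equal(teac(14.9, 14.9), 1)
  expect_equal(round_half_up(teac(14.9, 3.83), 2), 3.89)
  expect_equal(round_half_up(teac(14.9, 66.52), 2), 0.22)
  expect_error(teac(14.9, 0), "positive")
  set.seed(2)
  for (k in 1:20) {
    v <- runif(3, 0.1, 50)
    expect_equal(teac(v[1], v[2]) * teac(v[2], v[3]), teac(v[1], v[3]),
                 tolerance = 1e-12)
  }
})

test_that("ORAC normalization anchors curves at the blank's f(0)", {
  t <- seq(0, 120, 15)
  blank <- orac_curve("blank", 0, t, 1000 * exp(-t / 40))
  same <- orac_normalize(blank, blank)
  expect_equal(same$fluorescence, blank$fluorescence)
  doubled <- orac_curve("s", 1, t, 2 * blank$fluorescence)
  norm <- orac_normalize(doubled, blank)
  expect_equal(norm$fluorescence, blank$fluorescence)
  arbitrary <- orac_curve("s", 1, t, 321 * exp(-t / 25))
  expect_equal(orac_normalize(arbitrary, blank)$fluorescence[1],
               blank$fluorescence[1])
  short <- orac_curve("s", 1, seq(0, 60, 15), rep(5, 5))
  expect_error(orac_normalize(short, blank), "time grid")
})

test_that("ORAC AUC is the sum of fluorescence ratios including t = 0", {
  t <- seq(0, 120, 15)
  expect_equal(orac_auc(orac_curve("b", 0, t, rep(7, 9))), 9)
  expect_equal(orac_auc(orac_curve("b", 0, t, c(5, rep(0, 8)))), 1)
  # linear decay from f0 to 0 over 9 readings: 1 + 7/8 + ... + 0 = 4.5
  lin <- orac_curve("b", 0, t, seq(8, 0, -1))
  expect_equal(orac_auc(lin), 4.5)
  expect_equal(orac_auc(lin, include_t0 = FALSE), 3.5)
  # scale invariance
  expect_equal(orac_auc(orac_curve("b", 0, t, 37.5 * seq(8, 0, -1))), 4.5)
})

test_that("Trolox equivalents are net-AUC regression slope ratios", {
  pts <- data.frame(conc = c(1, 2, 4, 8), net_auc = c(0.5, 1.1, 2.0, 4.1))
  expect_equal(orac_trolox_equivalents(pts, pts)$trolox_eq, 1)
  double <- transform(pts, net_auc = 2 * net_auc)
  expect_equal(orac_trolox_equivalents(double, pts)$trolox_eq, 2)
  flat <- data.frame(conc = c(1, 2, 4), net_auc = c(1, 1, 1))
  expect_error(orac_trolox_equivalents(pts, flat), "Trolox slope")
  sing <- data.frame(conc = c(2, 2), net_auc = c(1, 2))
  expect_error(orac_trolox_equivalents(sing, pts), "singular")
})

test_that("ID50 x TEAC is constant across the printed activity panel", {
  t4 <- tea_activity_table()
  for (a in c("dpph", "abts", "tbars")) {
    prod <- t4[[paste0("id50_", a)]] * t4[[paste0("teac_", a)]]
    expect_lt(max(abs(prod / mean(prod) - 1)), 0.05)
  }
})
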