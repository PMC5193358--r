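test_that("single-DOF worked example returns 91.2 W exactly", {
  tr <- gait_trial(t = c(0, 1), q = cbind(j = c(0, 1)), qd = cbind(j = c(1, 1)),
                   tau = cbind(j = c(10, 10)), v = c(1.3, 1.3))
  trace <- mee_rate(tr, list(h_am = 0.02, h_sl = 0.1), bmr = 80)
  expect_identical(trace$e_met, c(91.2, 91.2))
  expect_equal(trace$work_rate, c(10, 10))
  expect_equal(trace$q_am, c(0.2, 0.2))
  expect_equal(trace$q_sl, c(1, 1))
})

test_that("a rest trial expends exactly the BMR", {
  n <- 50
  z <- matrix(0, n, 2, dimnames = list(NULL, c("a", "b")))
  tr <- gait_trial(seq(0, 1, length.out = n), z, z, z, v = rep(1.1, n))
  trace <- mee_rate(tr, list(h_am = c(0.1, 0.1), h_sl = c(1, 1)), bmr = 77)
  expect_true(all(trace$e_met == 77))
})

test_that("model is invariant to joint sign conventions", {
  tr <- smooth_trial()
  h <- list(h_am = c(0.1, 0.08), h_sl = c(1.2, 1.1))
  t1 <- mee_rate(tr, h, bmr = 80)
  tr2 <- gait_trial(tr$t, -tr$q, -tr$qd, -tr$tau, tr$v)
  t2 <- mee_rate(tr2, h, bmr = 80)
  expect_equal(t1$e_met, t2$e_met)
})

test_that("trace components are additive at every sample", {
  tr <- smooth_trial(n = 300, ndof = 2)
  trace <- mee_rate(tr, list(h_am = c(0.05, 0.2), h_sl = c(1.5, 1.0)), bmr = 90)
  recon <- trace$work_rate + trace$q_am + trace$q_sl + trace$q_cc + trace$bmr
  expect_rel_equal(trace$e_met, recon, 1e-10)
  expect_true(all(trace$q_am >= 0 & trace$q_sl >= 0 & trace$q_cc >= 0))
})

test_that("ICOT is the pointwise MEE rate per unit weight-speed", {
  tr <- smooth_trial()
  trace <- mee_rate(tr, list(h_am = c(0.1, 0.1), h_sl = c(1, 1)), bmr = 80)
  sub <- subject_profile("s", "M", 70, 1.75, 30, 200, bmr = 80)
  ic <- icot(trace, sub)
  # identity: ICOT * M g v == e_met, pointwise
  expect_rel_equal(ic * 70 * 9.81 * attr(trace, "v"), trace$e_met, 1e-12)
  # forced arithmetic
  expect_equal(icot(trace, 70, v = rep(1.3, nrow(trace)))[1],
               trace$e_met[1] / (70 * 9.81 * 1.3))
  expect_equal(300 / (70 * 9.81 * 1.3), 0.336, tolerance = 1e-3)
  # doubling speed halves ICOT
  expect_rel_equal(icot(trace, sub, v = 2 * attr(trace, "v")), ic / 2, 1e-12)
  # domain error carries the sample index
  bad_v <- attr(trace, "v"); bad_v[7] <- 0
  expect_error(icot(trace, sub, v = bad_v), "7")
})

test_that("COT of constant traces is the closed form E0/(M g v0)", {
  n <- 40
  z <- matrix(0, n, 1, dimnames = list(NULL, "a"))
  tr <- gait_trial(seq(0, 2, length.out = n), z, z, z, v = rep(1.25, n))
  trace <- mee_rate(tr, list(h_am = 0.1, h_sl = 1), bmr = 84)
  sub <- subject_profile("s", "M", 80, 1.8, 30, 200, bmr = 84)
  # rest trial on a belt at v0: COT = BMR / (M g v0), over any interval
  expect_rel_equal(cot(trace, subject = sub), 84 / (80 * 9.81 * 1.25), 1e-12)
  expect_rel_equal(cot(trace, c(0.3, 0.9), sub), 84 / (80 * 9.81 * 1.25), 1e-12)
})

test_that("COT matches a dense Riemann-sum oracle on smooth traces", {
  # analytic integrand: rebuild e_met and v as closed forms
  T <- 1.2
  e_fun <- function(t) 250 + 60 * sin(2 * pi * t / T) + 25 * cos(4 * pi * t / T)
  v_fun <- function(t) 1.3 + 0.12 * sin(2 * pi * t / T + 0.5)
  n <- 240
  t <- seq(0, T, length.out = n + 1L)
  z <- matrix(0, n + 1L, 1, dimnames = list(NULL, "a"))
  tr <- gait_trial(t, z, z, z, v = v_fun(t))
  trace <- mee_rate(tr, list(h_am = 0, h_sl = 0), bmr = 0)
  trace$e_met <- e_fun(t)  # imposed analytic profile
  sub <- subject_profile("s", "M", 70, 1.7, 30, 200, bmr = 80)
  for (iv in list(c(0, T), c(0.11, 0.97))) {
    dense_e <- riemann_integral(e_fun, iv[1], iv[2], n = 2e5)
    dense_v <- riemann_integral(v_fun, iv[1], iv[2], n = 2e5)
    oracle <- dense_e / (70 * 9.81 * dense_v)
    # trapezoid on the 240-sample grid vs near-exact quadrature: the
    # comparison tolerance reflects the grid truncation error
    expect_rel_equal(cot(trace, iv, sub), oracle, 1e-4)
  }
  # grid-refinement: 100x finer grid agrees with the dense oracle to 1e-8
  t2 <- seq(0, T, length.out = 100 * n + 1L)
  z2 <- matrix(0, length(t2), 1, dimnames = list(NULL, "a"))
  tr2 <- gait_trial(t2, z2, z2, z2, v = v_fun(t2))
  trace2 <- mee_rate(tr2, list(h_am = 0, h_sl = 0), bmr = 0)
  trace2$e_met <- e_fun(t2)
  dense_e <- riemann_integral(e_fun, 0, T, n = 2e6)
  dense_v <- riemann_integral(v_fun, 0, T, n = 2e6)
  expect_rel_equal(cot(trace2, c(0, T), sub), dense_e / (70 * 9.81 * dense_v),
                   1e-8)
})

test_that("COT over a union of disjoint intervals pools the integrals", {
  tr <- smooth_trial(n = 400)
  trace <- mee_rate(tr, list(h_am = c(0.1, 0.1), h_sl = c(1, 1)), bmr = 80)
  sub <- subject_profile("s", "M", 70, 1.7, 30, 200, bmr = 80)
  iv <- rbind(c(0.1, 0.4), c(0.6, 0.9))
  # direct evaluation of the duration-weighted combination
  int_e <- sum(apply(iv, 1, function(r)
    gaitmee:::interval_integral(trace$time, trace$e_met, r[1], r[2])))
  int_v <- sum(apply(iv, 1, function(r)
    gaitmee:::interval_integral(trace$time, attr(trace, "v"), r[1], r[2])))
  expect_rel_equal(cot(trace, iv, sub), int_e / (70 * 9.81 * int_v), 1e-12)
})

test_that("component breakdown conserves the total and ignores time shifts", {
  tr <- smooth_trial(n = 150)
  trace <- mee_rate(tr, list(h_am = c(0.1, 0.2), h_sl = c(1.1, 1.3)), bmr = 95)
  br <- component_breakdown(trace)
  parts <- br$energy_J[br$component != "e_met"]
  total <- br$energy_J[br$component == "e_met"]
  expect_rel_equal(sum(parts), total, 1e-9)
  expect_rel_equal(sum(br$share_pct[br$component != "e_met"]), 100, 1e-9)
  # rest trial: all energy is BMR
  z <- matrix(0, 30, 1, dimnames = list(NULL, "a"))
  rest <- mee_rate(gait_trial(seq(0, 1, length.out = 30), z, z, z,
                              v = rep(1, 30)),
                   list(h_am = 0.1, h_sl = 1), bmr = 70)
  brr <- component_breakdown(rest)
  expect_equal(brr$share_pct[brr$component == "bmr"], 100)
  # uniform time shift leaves shares unchanged
  tr2 <- gait_trial(tr$t + 5, tr$q, tr$qd, tr$tau, tr$v)
  trace2 <- mee_rate(tr2, list(h_am = c(0.1, 0.2), h_sl = c(1.1, 1.3)), bmr = 95)
  expect_equal(component_breakdown(trace2)$share_pct, br$share_pct)
})

test_that("gait_trial rejects malformed input", {
  z <- matrix(0, 3, 1, dimnames = list(NULL, "a"))
  expect_error(gait_trial(c(0, 1, 1), z, z, z, v = rep(1, 3)),
               "strictly increasing")
  expect_error(gait_trial(c(0, 0.5, 2), z, z, z, v = rep(1, 3)), "uniform")
  expect_error(gait_trial(0:2, z, z, z, v = rep(1, 3), qcc = z - 1),
               "second-law")
  expect_error(mee_rate(gait_trial(0:2, z, z, z, v = rep(1, 3)),
                        list(h_am = -0.1, h_sl = 1), bmr = 80),
               "non-negative")
})
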