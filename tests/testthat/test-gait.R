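test_that("GRF threshold detector finds constructed contact windows", {
  n <- 1200
  t <- seq(0, 2, length.out = n)
  z <- matrix(0, n, 1, dimnames = list(NULL, "a"))
  # square-wave stance: right [0.2, 1.0] and [1.4, 2.0]; left [0.8, 1.6]
  grf <- list(right = 800 * ((t >= 0.2 & t <= 1.0) | t >= 1.4),
              left = 800 * (t >= 0.8 & t <= 1.6))
  tr <- gait_trial(t, z, z, z, v = rep(1, n), grf = grf)
  ev <- detect_gait_events(tr, threshold = 20, hysteresis = 5)
  dt <- t[2] - t[1]
  rhs <- ev$time[ev$side == "right" & ev$type == "heel_strike"]
  expect_equal(length(rhs), 2L)
  expect_lt(abs(rhs[1] - 0.2), dt)
  expect_lt(abs(rhs[2] - 1.4), dt)
  lto <- ev$time[ev$side == "left" & ev$type == "toe_off"]
  expect_lt(abs(lto - 1.6), dt)
  # time-shift equivariance
  tr2 <- gait_trial(t + 3, z, z, z, v = rep(1, n), grf = grf)
  ev2 <- detect_gait_events(tr2)
  expect_rel_equal(ev2$time, ev$time + 3, 1e-9)
  # fewer than two right heel strikes
  tr3 <- gait_trial(t, z, z, z, v = rep(1, n),
                    grf = list(right = 800 * (t >= 0.2 & t <= 1.0),
                               left = grf$left))
  expect_error(detect_gait_events(tr3), "no complete stride")
})

test_that("segmentation recovers the generator's double-support fraction", {
  cfg <- generator_config(seed = 5)
  set.seed(5)
  sub <- generate_subject(cfg, "s", "M")
  trial <- generate_gait_trial(sub, 1.2, cfg)
  seg <- segment_phases(trial$events)
  # events are analytic: exact recovery
  expect_equal(seg$fractions$ds_pct, attr(trial, "ds_pct"), tolerance = 1e-9)
  expect_equal(seg$fractions$ds_pct + seg$fractions$ss_pct, 100)
  # durations conserve the stride time
  ph <- seg$phases
  expect_rel_equal(sum(ph$duration), diff(range(seg$strides)), 1e-9)
  # detector + segmentation on a two-stride square-wave GRF with 30% DS
  T <- 1.1; dsh <- 0.30 * T / 2
  n <- 2200
  t <- seq(0, 2 * T, length.out = n)
  tt <- t %% T
  stance_r <- tt <= T / 2 + dsh
  stance_l <- tt >= T / 2 | tt <= dsh
  z <- matrix(0, n, 1, dimnames = list(NULL, "a"))
  trial2 <- gait_trial(t, z, z, z, v = rep(1.2, n),
                       grf = list(right = 900 * stance_r, left = 900 * stance_l))
  seg2 <- segment_phases(detect_gait_events(trial2))
  expect_lt(abs(seg2$fractions$ds_pct[1] - 30), 0.5)
})

test_that("instantaneous double support yields a zero DS fraction", {
  T <- 1
  ev <- data.frame(side = c("right", "left", "left", "right", "right"),
                   type = c("heel_strike", "toe_off", "heel_strike",
                            "toe_off", "heel_strike"),
                   time = c(0, 0, T / 2, T / 2, T))
  seg <- segment_phases(ev)
  expect_equal(seg$fractions$ds_pct, 0)
  expect_equal(seg$fractions$ss_pct, 100)
})

test_that("out-of-order events are reported with their position", {
  ev <- stride_events(1, 30)
  ev$type[2] <- "heel_strike"  # left heel strike before its toe off
  ev$side[2] <- "left"
  expect_error(segment_phases(ev), "stride 1")
})

test_that("bilateral synchronization splits the left stride at right heel strike", {
  cfg <- generator_config(seed = 9, samples_per_stride = 60)
  set.seed(9)
  sub <- generate_subject(cfg, "s", "M")
  cat42 <- default_dof_catalog("M")
  full <- generate_gait_trial(sub, 1.3, cfg, catalog = cat42)
  T <- diff(range(full$t))
  n <- length(full$t) - 1L           # even, so T/2 lies on the grid
  left_ids <- grep("_l_", full$dof_ids, value = TRUE)
  # fabricate a separately captured left stride: the same periodic data
  # shifted by half a period, carrying the right heel strike event inside
  half <- n / 2 + 1L
  wrap <- c(half:(n + 1L), 2:half)
  left <- gait_trial(seq(0, T, length.out = length(wrap)),
                     full$q[wrap, left_ids, drop = FALSE],
                     full$qd[wrap, left_ids, drop = FALSE],
                     full$tau[wrap, left_ids, drop = FALSE],
                     v = full$v[wrap],
                     events = data.frame(side = "right", type = "heel_strike",
                                         time = T / 2))
  sync <- synchronize_bilateral(full, left)
  expect_equal(diff(range(sync$t)), T)
  expect_setequal(sync$dof_ids, full$dof_ids)
  # round-trip: resampled left channels match the original trial
  err <- max(abs(sync$q[, left_ids] - full$q[, left_ids]))
  expect_lt(err, 1e-6)
})

test_that("Froude number follows v / sqrt(g * 0.53 H)", {
  expect_equal(froude_number(0, 1.7), 0)
  expect_equal(0.53 * 1.70, 0.901)
  expect_equal(froude_number(1.29, 1.70), 0.4339032, tolerance = 1e-6)
  # invariance under v -> k v, l -> k^2 l
  fr1 <- froude_number(1.2, 1.7)
  fr2 <- froude_number(2 * 1.2, 4 * 1.7)
  expect_rel_equal(fr2, fr1, 1e-12)
  expect_error(froude_number(1, -1), "height")
})

test_that("Laurent COT fit recovers exact coefficients and the argmin", {
  v <- seq(0.8, 1.8, by = 0.2)
  cotv <- 0.2 / v + 0.1 + 0.1 * v
  fit <- fit_cot_curve(v, cotv)
  expect_rel_equal(unname(fit$coefficients), c(0.2, 0.1, 0.1), 1e-8)
  expect_rel_equal(fit$argmin, sqrt(2), 1e-8)
  expect_true(fit$convex)
  # constant data
  fit0 <- fit_cot_curve(v, rep(0.35, length(v)))
  expect_equal(unname(fit0$coefficients), c(0, 0.35, 0), tolerance = 1e-10)
  # residuals invariant to point ordering
  o <- sample(length(v))
  fit_p <- fit_cot_curve(v[o], (cotv + 0.01 * sin(v))[o])
  fit_q <- fit_cot_curve(v, cotv + 0.01 * sin(v))
  expect_rel_equal(sum(fit_p$residuals^2), sum(fit_q$residuals^2), 1e-10)
  expect_error(fit_cot_curve(c(1, 1, 1.2), c(0.3, 0.31, 0.29)),
               "3 distinct")
})

test_that("phase-specific COT conserves shares and detects DS-loaded strides", {
  n <- 600
  T <- 1.2
  t <- seq(0, T, length.out = n)
  z <- matrix(0, n, 1, dimnames = list(NULL, "a"))
  ev <- stride_events(T, 30)
  sub <- subject_profile("s", "M", 75, 1.8, 30, 200, bmr = 80)
  tr <- gait_trial(t, z, z, z, v = rep(1.3, n), events = ev)
  trace <- mee_rate(tr, list(h_am = 0.1, h_sl = 1), bmr = 80)
  seg <- segment_phases(ev)
  pc <- phase_cot(trace, seg, sub)
  # constant e_met and v: phase COTs all equal the total
  expect_rel_equal(c(pc$cot_ss, pc$cot_ds), rep(pc$cot_total, 2), 1e-9)
  expect_rel_equal(pc$duration_ss_pct + pc$duration_ds_pct, 100, 1e-9)
  expect_rel_equal(pc$mee_ss_pct + pc$mee_ds_pct, 100, 1e-9)
  # double e_met during DS samples only: DS energy share must exceed its
  # duration share
  in_ds <- (t <= 0.15) | (t >= T / 2 & t <= T / 2 + 0.15)
  trace2 <- trace
  trace2$e_met[in_ds] <- 2 * trace2$e_met[in_ds]
  pc2 <- phase_cot(trace2, seg, sub)
  expect_gt(pc2$mee_ds_pct, pc2$duration_ds_pct)
})

test_that("correlation screen matches the covariance formula", {
  set.seed(31)
  d <- data.frame(mass = runif(12, 50, 100), height = runif(12, 1.5, 1.95),
                  age = runif(12, 20, 45))
  d$mee <- 3.2 * d$mass + rnorm(12, 0, 5)
  res <- parameter_correlations(d)
  # textbook covariance-formula oracle
  oracle_r <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  for (p in c("mass", "height", "age")) {
    expect_rel_equal(res$r[res$parameter == p], oracle_r(d[[p]], d$mee), 1e-12)
  }
  # exactly linear response
  d2 <- data.frame(mass = 1:10, mee = 2 * (1:10) + 3)
  expect_equal(parameter_correlations(d2)$r, 1)
  # constant column flagged
  d3 <- data.frame(mass = rep(70, 5), mee = rnorm(5))
  expect_equal(parameter_correlations(d3)$flag, "undefined-constant")
  expect_error(parameter_correlations(data.frame(mass = 1:2, mee = 1:2)),
               "3 subjects")
})
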