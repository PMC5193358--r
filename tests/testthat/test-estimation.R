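# small shared dataset: 2 subjects x 3 speeds, reduced grid, zero noise
small_sim <- local({
  cfg <- generator_config(seed = 301, n_subjects = 2, n_validation = 2,
                          speeds_pct = c(70, 100, 130),
                          samples_per_stride = 40, noise_sd = 0)
  generate_dataset(cfg)
})

test_that("objective vanishes for self-consistent data and matches brute force", {
  ds <- small_sim$estimation
  wv <- c(published_weights()$am, published_weights()$sl)
  expect_lt(mee_objective(wv, ds), 1e-18)
  # brute-force oracle: recompute each stride average through the full
  # trace machinery, then the mean squared residual directly
  w2 <- wv * 1.05
  brute <- local({
    resid <- c()
    for (e in unclass(ds)) {
      h <- heat_coefficients(weight_parameters(w2[1:5], w2[6:10]),
                             e$subject, e$catalog, check = FALSE)
      for (k in seq_along(e$trials)) {
        trace <- mee_rate(e$trials[[k]], h, e$subject)
        avg <- gaitmee:::interval_integral(trace$time, trace$e_met,
                                           min(trace$time), max(trace$time)) /
          diff(range(trace$time))
        resid <- c(resid, e$measured[k] - avg)
      }
    }
    sum(resid^2) / (2 * length(resid))
  })
  expect_rel_equal(mee_objective(w2, ds), brute, 1e-12)
  # invariance to stride ordering
  ds_rev <- estimation_dataset(rev(unclass(ds)))
  expect_rel_equal(mee_objective(w2, ds_rev), mee_objective(w2, ds), 1e-12)
})

test_that("analytic gradients match central differences", {
  prep <- gaitmee:::prepare_estimation(small_sim$estimation)
  wv <- c(published_weights()$am, published_weights()$sl) * 1.2 +
    c(rep(2e-5, 4), 50, rep(0.03, 4), 2e-3)
  og <- gaitmee:::objective_grad(prep, wv)
  num <- vapply(1:10, function(i) {
    h <- abs(wv[i]) * 1e-6 + 1e-12
    wp <- wv; wm <- wv; wp[i] <- wp[i] + h; wm[i] <- wm[i] - h
    (mee_objective(wp, prep) - mee_objective(wm, prep)) / (2 * h)
  }, numeric(1))
  expect_rel_equal(og$grad, num, 1e-5)
  set.seed(1)
  mu <- runif(length(gaitmee:::constraint_eval(prep, wv)))
  cg <- gaitmee:::constraint_eval(prep, wv, want_grad = TRUE, mu = mu)
  numc <- vapply(1:10, function(i) {
    h <- abs(wv[i]) * 1e-6 + 1e-12
    wp <- wv; wm <- wv; wp[i] <- wp[i] + h; wm[i] <- wm[i] - h
    (sum(mu * gaitmee:::constraint_eval(prep, wp)) -
       sum(mu * gaitmee:::constraint_eval(prep, wm))) / (2 * h)
  }, numeric(1))
  expect_rel_equal(cg, numc, 1e-5)
})

test_that("constraint margins at w = 0 take their closed-form values", {
  ds <- small_sim$estimation
  con <- suppressWarnings(mee_constraints(rep(0, 10), ds))
  expect_true(all(con$first_factors == 0))
  expect_true(all(con$second_factors$am == 1))
  expect_true(all(con$second_factors$sl == 1))
  # net-MEE margin reduces to tau * qd pointwise; aggregated: its minimum
  prep <- gaitmee:::prepare_estimation(ds)
  expect_equal(min(con$net_mee), min(prep$TQ))
  expect_true(all(con$energy_bounds$lower > 0))  # BMR + heat-free work avg
})

test_that("published weights are feasible for group-mean subjects", {
  z <- matrix(0, 11, 1, dimnames = list(NULL, "hip_r_sag"))
  mk <- function(sub) {
    cat1 <- default_dof_catalog(sub$sex)
    idm <- matrix(0, 11, 42, dimnames = list(NULL, cat1$dof_id))
    trial <- gait_trial(seq(0, 1, length.out = 11), idm, idm, idm,
                        v = rep(1.3, 11))
    list(subject = sub, catalog = cat1, trials = list(trial),
         measured = sub$bmr, speed = 1.3)
  }
  ds <- estimation_dataset(list(mk(male_mean_subject()),
                                mk(female_mean_subject())))
  wv <- c(published_weights()$am, published_weights()$sl)
  con <- suppressWarnings(mee_constraints(wv, ds))
  expect_true(all(con$first_factors >= 0))
  expect_true(all(con$second_factors$am >= 0 & con$second_factors$sl >= 0))
})

test_that("net-MEE margin flags strongly eccentric samples by construction", {
  # one DOF, tau*qd < -(h_am|tau| + h_sl|tau*qd|) forces a violation
  t <- seq(0, 1, length.out = 21)
  tau <- cbind(hip_r_sag = rep(40, 21))
  qd <- cbind(hip_r_sag = rep(-2, 21))
  q <- qd * 0
  trial <- gait_trial(t, q, qd, tau, v = rep(1.3, 21))
  filler <- matrix(0, 21, 41)
  cat1 <- default_dof_catalog("M")
  colnames(filler) <- setdiff(cat1$dof_id, "hip_r_sag")
  trial_full <- gait_trial(t, cbind(q, filler), cbind(qd, filler),
                           cbind(tau, filler), v = rep(1.3, 21))
  ds <- estimation_dataset(list(list(subject = male_mean_subject(),
                                     catalog = cat1, trials = list(trial_full),
                                     measured = 300, speed = 1.3)))
  # weights with tiny h_am and h_sl < 1: margin = tau qd (1 - h_sl) + ...< 0
  w_bad <- c(1e-6, 0, 0, 0, 0, 0.5, 0, 0, 0, 0)
  con <- suppressWarnings(mee_constraints(w_bad, ds))
  expect_lt(con$worst[["net_mee"]], 0)
})

test_that("one-subject one-speed data are interpolated exactly", {
  cfg <- generator_config(seed = 33, n_subjects = 1, n_validation = 0,
                          speeds_pct = 100, samples_per_stride = 30,
                          noise_sd = 0.04)
  cfg$n_validation <- 0L
  set.seed(33)
  sub <- generate_subject(cfg, "only", "M")
  cat1 <- default_dof_catalog("M")
  trial <- generate_gait_trial(sub, 1.3, cfg, catalog = cat1)
  ds <- estimation_dataset(list(list(subject = sub, catalog = cat1,
                                     trials = list(trial), measured = 340,
                                     speed = 1.3)))
  fit <- fit_mee(ds, mee_control(seed = 2, multistart = 2))
  expect_lt(fit$objective, 1e-10)
})

test_that("fitting recovers held-out predictions and satisfies constraints", {
  fit <- fit_mee(small_sim$estimation, mee_control(seed = 4, multistart = 2))
  # monotone improvement: returned optimum beats both start objectives
  starts <- fit$convergence$starts
  expect_true(all(fit$objective <= starts$objective + 1e-12))
  expect_gt(min(fit$constraints$worst[c("first_factor", "second_factor",
                                        "net_mee", "energy_lower")],
                na.rm = TRUE), -1e-8)
  # zero-noise data: near-interpolation and held-out accuracy
  expect_lt(sqrt(2 * fit$objective) / mean(fit$measured), 0.005)
  val <- validate_mee(fit$weights, small_sim$validation)
  expect_lt(val$mean_abs_pct_error, 1)
  # determinism: same seed, same result
  fit2 <- fit_mee(small_sim$estimation, mee_control(seed = 4, multistart = 2))
  expect_identical(coef(fit), coef(fit2))
})

test_that("model methods expose the fit consistently", {
  fit <- fit_mee(small_sim$estimation, mee_control(seed = 4, multistart = 1))
  expect_length(coef(fit), 10L)
  expect_equal(fitted(fit) + residuals(fit), fit$measured)
  expect_equal(predict(fit), fitted(fit))
  pred_val <- predict(fit, newdata = small_sim$validation)
  expect_length(pred_val, attr(small_sim$validation, "N"))
  s <- summary(fit)
  expect_s3_class(s, "summary.mee_fit")
  expect_true(is.finite(s$r_squared))
  sims <- simulate(fit, nsim = 3, seed = 1, sd_rel = 0.02)
  expect_equal(dim(sims), c(length(fitted(fit)), 3L))
  expect_output(print(fit), "heat-coefficient weights")
})

test_that("validation statistics match their direct formulas", {
  ds <- small_sim$validation
  wv <- c(published_weights()$am, published_weights()$sl)
  val <- validate_mee(wv, ds)
  # generating weights on zero-noise data: errors are numerically zero
  expect_lt(val$mean_abs_pct_error, 1e-10)
  expect_rel_equal(val$r_squared_inter, 1, 1e-10)
  # R^2 equals the squared covariance-formula correlation
  tab <- val$table
  tab$model <- tab$model * (1 + 0.01 * sin(seq_len(nrow(tab))))
  r <- sum((tab$model - mean(tab$model)) * (tab$measured - mean(tab$measured))) /
    sqrt(sum((tab$model - mean(tab$model))^2) *
           sum((tab$measured - mean(tab$measured))^2))
  ds_jit <- ds
  expect_rel_equal(stats::cor(tab$model, tab$measured)^2, r^2, 1e-12)
  # constant measured values: undefined inter-subject correlation flagged
  const <- lapply(unclass(ds), function(e) { e$measured[] <- 300; e })
  valc <- validate_mee(wv, estimation_dataset(const))
  expect_true(is.na(valc$r_squared_inter))
})

test_that("rescaling measurements and BMR rescales the rest component", {
  c_fac <- 1.7
  scaled <- lapply(unclass(small_sim$estimation), function(e) {
    e$subject$bmr <- e$subject$bmr * c_fac
    e$measured <- e$measured * c_fac
    e
  })
  ds_s <- estimation_dataset(scaled)
  fit_s <- fit_mee(ds_s, mee_control(seed = 4, multistart = 2))
  # a rest trial (zero torque) predicts BMR exactly, which scaled by c
  z <- matrix(0, 5, 42)
  colnames(z) <- scaled[[1]]$catalog$dof_id
  rest <- gait_trial(seq(0, 1, length.out = 5), z, z, z, v = rep(1, 5))
  rest_ds <- estimation_dataset(list(list(
    subject = scaled[[1]]$subject, catalog = scaled[[1]]$catalog,
    trials = list(rest), measured = scaled[[1]]$subject$bmr, speed = 1)))
  expect_rel_equal(predict(fit_s, rest_ds), scaled[[1]]$subject$bmr, 1e-12)
})
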