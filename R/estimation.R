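#' Estimation dataset
#'
#' Pairs each subject's gait strides with the measured per-condition mean
#' metabolic rate. Every stride maps to exactly one measured value
#' \eqn{\bar{E}_{met}} (W).
#'
#' @param entries A list; each element is a list with components
#'   `subject` (a [subject_profile()]), `trials` (list of single-stride
#'   [gait_trial()]s), `measured` (numeric, W, one per trial), `speed`
#'   (numeric, m/s, one per trial) and optionally `catalog` (a
#'   [dof_catalog()]; defaults to [default_dof_catalog()] for the
#'   subject's sex).
#' @return An object of class `"estimation_dataset"` with attribute `N`
#'   (total stride count).
#' @export
estimation_dataset <- function(entries) {
  if (!length(entries)) stop("estimation_dataset: no entries", call. = FALSE)
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    if (!inherits(e$subject, "subject_profile")) {
      stop("estimation_dataset: entry ", k, " has no subject_profile", call. = FALSE)
    }
    if (!length(e$trials) || !all(vapply(e$trials, inherits, logical(1L), "gait_trial"))) {
      stop("estimation_dataset: entry ", k, " has invalid trials", call. = FALSE)
    }
    if (length(e$measured) != length(e$trials) || any(!is.finite(e$measured))) {
      stop("estimation_dataset: entry ", k,
           ": 'measured' must map one finite value to each trial", call. = FALSE)
    }
    if (is.null(e$catalog)) {
      entries[[k]]$catalog <- default_dof_catalog(e$subject$sex)
    }
  }
  N <- sum(vapply(entries, function(e) length(e$trials), integer(1L)))
  structure(entries, N = N, class = "estimation_dataset")
}

#' @export
print.estimation_dataset <- function(x, ...) {
  cat(sprintf("Estimation dataset: %d subject(s), %d stride(s)\n",
              length(x), attr(x, "N")))
  invisible(x)
}

# trapezoid quadrature weights for a time average over a uniform grid
trapz_avg_weights <- function(t) {
  n <- length(t)
  w <- rep(1, n); w[c(1L, n)] <- 0.5
  w / (n - 1L)
}

# Reduce a dataset to the sufficient statistics of the weight estimation:
# per-stride time-averaged work rate and per-DOF torque / power magnitude
# averages (the model's stride-average MEE is affine in the products of the
# two weight factors), plus stacked per-sample matrices for the
# non-negative-net-MEE constraint.
prepare_estimation <- function(dataset) {
  stopifnot(inherits(dataset, "estimation_dataset"))
  subjects <- list()
  stride_rows <- list()
  TQ <- list(); AT <- list(); AP <- list(); row_subject <- list()
  for (s in seq_along(dataset)) {
    e <- dataset[[s]]
    np <- normalize_parameters(e$subject, e$catalog)
    subjects[[s]] <- list(id = e$subject$id, u = c(1, np$m_n, np$a_n, np$h_n),
                          r = np$knee_ratio, taun = np$tau_n,
                          bmr = e$subject$bmr, vo2max = e$subject$vo2max)
    for (k in seq_along(e$trials)) {
      tr <- e$trials[[k]]
      idx <- match(e$catalog$dof_id, tr$dof_ids)
      if (anyNA(idx)) {
        stop("prepare_estimation: trial DOFs do not cover catalog for subject ",
             e$subject$id, call. = FALSE)
      }
      tau <- tr$tau[, idx, drop = FALSE]
      qd <- tr$qd[, idx, drop = FALSE]
      wq <- trapz_avg_weights(tr$t)
      tq <- tau * qd
      at <- abs(tau)
      ap <- abs(tq)
      abar <- drop(crossprod(at, wq))
      pbar <- drop(crossprod(ap, wq))
      stride_rows[[length(stride_rows) + 1L]] <- data.frame(
        subject = s, speed = e$speed[k], measured = e$measured[k],
        duration = diff(range(tr$t)),
        Wbar = sum(drop(crossprod(tq, wq))),
        SA = sum(abar), SAt = sum(np$tau_n * abar),
        SP = sum(pbar), SPt = sum(np$tau_n * pbar))
      TQ[[length(TQ) + 1L]] <- tq
      AT[[length(AT) + 1L]] <- at
      AP[[length(AP) + 1L]] <- ap
      row_subject[[length(row_subject) + 1L]] <- rep(s, nrow(tau))
    }
  }
  list(subjects = subjects,
       strides = do.call(rbind, stride_rows),
       TQ = do.call(rbind, TQ), AT = do.call(rbind, AT),
       AP = do.call(rbind, AP),
       row_subject = unlist(row_subject),
       taun_mat = do.call(rbind, lapply(subjects, `[[`, "taun")))
}

as_weight_vector <- function(w) {
  if (inherits(w, "weight_parameters")) c(w$am, w$sl) else {
    if (length(w) != 10L) stop("weights must have 10 elements", call. = FALSE)
    as.numeric(w)
  }
}

# per-subject coefficient pieces under weight vector wv
subject_coefficients <- function(prep, wv) {
  U <- do.call(rbind, lapply(prep$subjects, `[[`, "u"))   # S x 4
  r <- vapply(prep$subjects, `[[`, numeric(1L), "r")
  f1_am <- drop(U %*% wv[1:4])
  f1_sl <- drop(U %*% wv[6:9])
  f2_am <- 1 + wv[5] * r * prep$taun_mat                  # S x nDOF
  f2_sl <- 1 + wv[10] * r * prep$taun_mat
  list(U = U, r = r, f1_am = f1_am, f1_sl = f1_sl,
       f2_am = f2_am, f2_sl = f2_sl,
       H_am = f1_am * f2_am, H_sl = f1_sl * f2_sl)
}

# model stride-average MEE rate (W) per stride
model_stride_average <- function(prep, wv) {
  sc <- subject_coefficients(prep, wv)
  st <- prep$strides
  s <- st$subject
  r <- sc$r[s]
  bmr <- vapply(prep$subjects, `[[`, numeric(1L), "bmr")[s]
  st$Wbar +
    sc$f1_am[s] * (st$SA + wv[5] * r * st$SAt) +
    sc$f1_sl[s] * (st$SP + wv[10] * r * st$SPt) + bmr
}

#' Estimation objective (mean squared stride residual)
#'
#' The least-squares cost of the weight estimation:
#' \deqn{error(w) = \frac{1}{2N}\sum_{k=1}^{N}
#'   \left(\bar{E}_{met,k} - \frac{1}{T_k}\int_{T_k}\dot{E}_{met}(t)\,dt
#'   \right)^2}
#' i.e. half the mean squared difference between each stride's measured
#' mean metabolic rate and the model's time-averaged rate over that
#' stride. The integral is divided by the stride duration so both terms
#' are rates in watts.
#'
#' @param w A [weight_parameters()] object or numeric vector of length 10
#'   (am weights then sl weights).
#' @param dataset An [estimation_dataset()] (or the internal prepared
#'   form).
#' @return The scalar objective value, in W^2.
#' @export
mee_objective <- function(w, dataset) {
  prep <- if (inherits(dataset, "estimation_dataset")) prepare_estimation(dataset) else dataset
  wv <- as_weight_vector(w)
  resid <- prep$strides$measured - model_stride_average(prep, wv)
  sum(resid^2) / (2 * nrow(prep$strides))
}

#' Thermodynamic constraint margins
#'
#' Evaluates the inequality-constraint margins of the weight estimation
#' (all must be non-negative at a feasible point):
#' \describe{
#'   \item{first factors}{subject factor of each coefficient function,
#'     \eqn{w_0 + w_1 m_n + w_2 a_n + w_3 h_n \ge 0}, per subject, am and sl.}
#'   \item{second factors}{DOF factor
#'     \eqn{1 + w_4 (\tau_{knee}^{max}/\tilde{\tau}_{knee}^{max})
#'     \tilde{\tau}_{n,i} \ge 0}, per subject and DOF.}
#'   \item{net MEE}{\eqn{\tau_i\dot{q}_i + h_i^{am}|\tau_i| +
#'     h_i^{sl}|\tau_i\dot{q}_i| \ge 0} at every sample (expended metabolic
#'     energy cannot be recharged by negative joint work); reported
#'     aggregated as the minimum over samples per subject and DOF, or per
#'     sample with `aggregate = FALSE`.}
#'   \item{energy bounds}{\eqn{0 \le \frac{1}{T}\int_T \dot{E}_{met}\,dt
#'     \le \dot{V}O_2max} per stride, reported only for subjects with a
#'     known \eqn{\dot{V}O_2max} (otherwise skipped with a warning).}
#' }
#'
#' @inheritParams mee_objective
#' @param aggregate If `TRUE` (default), reduce the per-sample net-MEE
#'   margins to their minimum per subject and DOF.
#' @return A list with elements `first_factors` (S x 2), `second_factors`
#'   (list of two S x nDOF matrices), `net_mee`, `energy_bounds`, and
#'   `worst` (named vector of the worst margin in each family).
#' @export
mee_constraints <- function(w, dataset, aggregate = TRUE) {
  prep <- if (inherits(dataset, "estimation_dataset")) prepare_estimation(dataset) else dataset
  wv <- as_weight_vector(w)
  sc <- subject_coefficients(prep, wv)
  ids <- vapply(prep$subjects, `[[`, character(1L), "id")
  ff <- cbind(am = sc$f1_am, sl = sc$f1_sl)
  rownames(ff) <- ids
  margin <- prep$TQ + prep$AT * sc$H_am[prep$row_subject, , drop = FALSE] +
    prep$AP * sc$H_sl[prep$row_subject, , drop = FALSE]
  if (aggregate) {
    net <- do.call(rbind, lapply(seq_along(prep$subjects), function(s) {
      rows <- prep$row_subject == s
      apply(margin[rows, , drop = FALSE], 2L, min)
    }))
    rownames(net) <- ids
  } else {
    net <- margin
  }
  vo2 <- vapply(prep$subjects, `[[`, numeric(1L), "vo2max")
  st <- prep$strides
  has_vo2 <- is.finite(vo2[st$subject])
  if (any(!has_vo2)) {
    warning("mee_constraints: VO2max missing for ",
            sum(!is.finite(vo2)), " subject(s); upper energy bound skipped",
            call. = FALSE)
  }
  avg <- model_stride_average(prep, wv)
  eb <- data.frame(stride = seq_len(nrow(st)),
                   lower = avg,
                   upper = ifelse(has_vo2, vo2[st$subject] - avg, NA_real_))
  worst <- c(first_factor = min(ff),
             second_factor = min(sc$f2_am, sc$f2_sl),
             net_mee = min(net),
             energy_lower = min(eb$lower),
             energy_upper = if (any(has_vo2)) min(eb$upper, na.rm = TRUE) else NA_real_)
  list(first_factors = ff,
       second_factors = list(am = sc$f2_am, sl = sc$f2_sl),
       net_mee = net, energy_bounds = eb, worst = worst)
}

#' Control parameters for [fit_mee()]
#'
#' @param seed Integer seed for the multistart perturbations (default
#'   20161228).
#' @param multistart Number of starting points (default 8): the zero
#'   vector, the packaged published weights, and seeded Gaussian
#'   perturbations around both.
#' @param start_sd Standard deviation of the start perturbations on the
#'   internal (scaled) parameters.
#' @param rho0,rho_mult Initial penalty parameter of the augmented
#'   Lagrangian and its growth factor.
#' @param outer_max Maximum augmented-Lagrangian (multiplier update)
#'   iterations per start.
#' @param inner_maxit Maximum BFGS iterations per inner solve.
#' @param tol_con Feasibility tolerance on scaled constraint margins.
#' @param tol_obj Convergence tolerance on the objective between outer
#'   iterations.
#' @param wscale Characteristic magnitude of each of the ten weights;
#'   optimization runs on `w / wscale`.
#' @return A list of class `"mee_control"`.
#' @export
mee_control <- function(seed = 20161228L, multistart = 8L, start_sd = 0.5,
                        rho0 = 100, rho_mult = 8, outer_max = 10L,
                        inner_maxit = 150L, tol_con = 1e-8, tol_obj = 1e-10,
                        wscale = c(1e-4, 1e-4, 1e-4, 1e-3, 1e3,
                                   1, 1, 1, 1, 1e-2)) {
  structure(list(seed = as.integer(seed), multistart = as.integer(multistart),
                 start_sd = start_sd, rho0 = rho0, rho_mult = rho_mult,
                 outer_max = as.integer(outer_max),
                 inner_maxit = as.integer(inner_maxit),
                 tol_con = tol_con, tol_obj = tol_obj, wscale = wscale),
            class = "mee_control")
}

# scaled constraint vector and its analytic gradient (10 x n_con) at wv.
# Families: (a) first factors / c_ff, (b) second factors, (c) per-sample
# net-MEE / c_w, (d) stride energy bounds / c_w.
con_scales <- list(ff_am = 1e-4, ff_sl = 1, f2 = 1, watts = 100)

constraint_eval <- function(prep, wv, want_grad = FALSE, mu = NULL) {
  sc <- subject_coefficients(prep, wv)
  S <- length(prep$subjects)
  nd <- ncol(prep$taun_mat)
  st <- prep$strides
  vo2 <- vapply(prep$subjects, `[[`, numeric(1L), "vo2max")
  has_vo2 <- is.finite(vo2[st$subject])
  margin <- prep$TQ + prep$AT * sc$H_am[prep$row_subject, , drop = FALSE] +
    prep$AP * sc$H_sl[prep$row_subject, , drop = FALSE]
  avg <- model_stride_average(prep, wv)
  g <- c(sc$f1_am / con_scales$ff_am,
         sc$f1_sl / con_scales$ff_sl,
         as.vector(sc$f2_am), as.vector(sc$f2_sl),
         as.vector(margin) / con_scales$watts,
         avg / con_scales$watts,
         (vo2[st$subject] - avg)[has_vo2] / con_scales$watts)
  if (!want_grad) return(g)
  # gradient of sum(mu * g) with respect to wv (used by the AL inner solve)
  stopifnot(length(mu) == length(g))
  i <- 0
  take <- function(n) { out <- mu[(i + 1):(i + n)]; i <<- i + n; out }
  mu_fa <- take(S); mu_fs <- take(S)
  mu_2a <- matrix(take(S * nd), S, nd); mu_2s <- matrix(take(S * nd), S, nd)
  mu_m <- matrix(take(length(margin)), nrow(margin), nd)
  mu_lo <- take(nrow(st)); mu_up <- take(sum(has_vo2))
  gr <- numeric(10L)
  U <- sc$U; r <- sc$r
  # (a) first factors
  gr[1:4] <- gr[1:4] + drop(crossprod(U, mu_fa)) / con_scales$ff_am
  gr[6:9] <- gr[6:9] + drop(crossprod(U, mu_fs)) / con_scales$ff_sl
  # (b) second factors: d/dw4 = r * taun
  gr[5] <- gr[5] + sum(mu_2a * (r * prep$taun_mat))
  gr[10] <- gr[10] + sum(mu_2s * (r * prep$taun_mat))
  # (c) net-MEE margins: h_am = f1_am * f2_am etc.
  MA <- mu_m * prep$AT   # weight on h_am per (row, dof)
  MP <- mu_m * prep$AP
  csA <- rowsum(MA, prep$row_subject)   # S x nd
  csP <- rowsum(MP, prep$row_subject)
  gr[1:4] <- gr[1:4] + drop(crossprod(U, rowSums(csA * sc$f2_am))) / con_scales$watts
  gr[6:9] <- gr[6:9] + drop(crossprod(U, rowSums(csP * sc$f2_sl))) / con_scales$watts
  gr[5] <- gr[5] + sum(sc$f1_am * rowSums(csA * (r * prep$taun_mat))) / con_scales$watts
  gr[10] <- gr[10] + sum(sc$f1_sl * rowSums(csP * (r * prep$taun_mat))) / con_scales$watts
  # (d) energy bounds: d avg / dw
  davg <- function(mu_st) {
    s <- st$subject
    out <- numeric(10L)
    ua <- (st$SA + wv[5] * r[s] * st$SAt) * mu_st
    us <- (st$SP + wv[10] * r[s] * st$SPt) * mu_st
    out[1:4] <- drop(crossprod(U[s, , drop = FALSE], ua))
    out[6:9] <- drop(crossprod(U[s, , drop = FALSE], us))
    out[5] <- sum(sc$f1_am[s] * r[s] * st$SAt * mu_st)
    out[10] <- sum(sc$f1_sl[s] * r[s] * st$SPt * mu_st)
    out
  }
  mu_stride <- mu_lo
  mu_stride_up <- numeric(nrow(st)); mu_stride_up[has_vo2] <- mu_up
  gr <- gr + (davg(mu_stride) - davg(mu_stride_up)) / con_scales$watts
  gr
}

objective_grad <- function(prep, wv) {
  sc <- subject_coefficients(prep, wv)
  st <- prep$strides
  s <- st$subject
  r <- sc$r
  bmr <- vapply(prep$subjects, `[[`, numeric(1L), "bmr")[s]
  avg <- st$Wbar + sc$f1_am[s] * (st$SA + wv[5] * r[s] * st$SAt) +
    sc$f1_sl[s] * (st$SP + wv[10] * r[s] * st$SPt) + bmr
  resid <- st$measured - avg
  N <- nrow(st)
  gr <- numeric(10L)
  coefa <- resid * (st$SA + wv[5] * r[s] * st$SAt)
  coefs <- resid * (st$SP + wv[10] * r[s] * st$SPt)
  gr[1:4] <- -drop(crossprod(sc$U[s, , drop = FALSE], coefa)) / N
  gr[6:9] <- -drop(crossprod(sc$U[s, , drop = FALSE], coefs)) / N
  gr[5] <- -sum(resid * sc$f1_am[s] * r[s] * st$SAt) / N
  gr[10] <- -sum(resid * sc$f1_sl[s] * r[s] * st$SPt) / N
  list(value = sum(resid^2) / (2 * N), grad = gr)
}

# Feasibility restoration: the net-MEE and first-factor margins are strictly
# increasing in the am/sl intercept weights (every coefficient is AT*f2_am or
# AP*f2_sl >= 0, and > 0 wherever a margin can be negative), and the second
# factors are restored by shrinking w4 toward zero. A solution that ends a
# hair outside the feasible set after the augmented-Lagrangian loop is moved
# strictly inside along these monotone directions; the objective perturbation
# is of the order of the (tiny) violation itself.
repair_feasibility <- function(prep, wv, max_iter = 60L) {
  # the strength term x = r * taun is positive, so only a negative w4 can
  # push a second factor 1 + w4 x below zero; project onto w4 >= -1/max(x)
  xmax <- max(vapply(prep$subjects, `[[`, numeric(1L), "r") * prep$taun_mat)
  if (1 + wv[5] * xmax < 0) wv[5] <- -0.999 / xmax
  if (1 + wv[10] * xmax < 0) wv[10] <- -0.999 / xmax
  for (it in seq_len(max_iter)) {
    sc <- subject_coefficients(prep, wv)
    # first factors
    if (min(sc$f1_am) < 0) wv[1] <- wv[1] - min(sc$f1_am) * 1.0001
    if (min(sc$f1_sl) < 0) wv[6] <- wv[6] - min(sc$f1_sl) * 1.0001
    sc <- subject_coefficients(prep, wv)
    margin <- prep$TQ + prep$AT * sc$H_am[prep$row_subject, , drop = FALSE] +
      prep$AP * sc$H_sl[prep$row_subject, , drop = FALSE]
    mmin <- min(margin)
    if (mmin >= 0) return(wv)
    # ascent coefficient of a joint unit increase of both intercepts
    lift <- prep$AT * sc$f2_am[prep$row_subject, , drop = FALSE] +
      prep$AP * sc$f2_sl[prep$row_subject, , drop = FALSE]
    viol <- margin < 0
    delta <- max((-margin[viol]) / pmax(lift[viol], 1e-12)) * 1.0001
    wv[1] <- wv[1] + delta
    wv[6] <- wv[6] + delta
  }
  wv
}

# Augmented-Lagrangian solve from one start (scaled coordinates z = w/wscale).
# The penalized value and gradient are computed in one pass and cached per
# point, so optim's separate fn/gr calls do not repeat the constraint sweep.
al_solve <- function(prep, z0, control) {
  ws <- control$wscale
  lambda <- numeric(length(constraint_eval(prep, z0 * ws)))
  rho <- control$rho0
  z <- z0
  prev_obj <- Inf
  status <- "max-outer"
  iters <- 0L
  cache <- new.env(parent = emptyenv())
  penalized <- function(zz, lambda, rho) {
    key <- zz
    if (!is.null(cache$key) && identical(cache$key, key)) return(cache$val)
    wv <- zz * ws
    ob <- objective_grad(prep, wv)
    g <- constraint_eval(prep, wv)
    a <- pmax(0, lambda - rho * g)
    gcon <- constraint_eval(prep, wv, want_grad = TRUE, mu = a)
    val <- list(value = ob$value + sum(a^2 - lambda^2) / (2 * rho),
                grad = (ob$grad - gcon) * ws,
                g = g, obj = ob$value)
    cache$key <- key; cache$val <- val
    val
  }
  for (outer in seq_len(control$outer_max)) {
    cache$key <- NULL  # multipliers changed; invalidate
    opt <- stats::optim(z, function(zz) penalized(zz, lambda, rho)$value,
                        function(zz) penalized(zz, lambda, rho)$grad,
                        method = "BFGS",
                        control = list(maxit = control$inner_maxit,
                                       reltol = 1e-13))
    z <- opt$par
    iters <- iters + opt$counts[["function"]]
    fin <- penalized(z, lambda, rho)
    viol <- max(0, -min(fin$g))
    obj <- fin$obj
    lambda <- pmax(0, lambda - rho * fin$g)
    # drive the solve an order tighter than the acceptance tolerance so
    # active constraints end within tol_con of the boundary
    if (viol <= control$tol_con / 10 && abs(prev_obj - obj) <= control$tol_obj *
        max(1, abs(obj))) {
      status <- "converged"
      break
    }
    # keep tightening the penalty so the multiplier iteration converges
    # quickly even after feasibility is reached
    rho <- min(rho * control$rho_mult, 1e10)
    prev_obj <- obj
  }
  list(z = z, w = z * ws, objective = obj, violation = viol,
       status = status, evals = iters, outer = outer)
}

#' Fit the heat-coefficient weights by constrained nonlinear least squares
#'
#' Minimizes [mee_objective()] over the ten weight parameters subject to
#' the thermodynamic inequality constraints of [mee_constraints()], using
#' a seeded multistart augmented-Lagrangian method: the non-negativity
#' constraints enter a smooth quadratic penalty with multiplier updates
#' (the net-MEE constraint is enforced at every sample of every stride),
#' and each inner problem is solved by BFGS with analytic gradients on
#' order-of-magnitude-scaled parameters. Starts are the zero vector, the
#' packaged published weights, and seeded perturbations of both; the best
#' feasible solution is returned. Deterministic given `control$seed`.
#'
#' @param dataset An [estimation_dataset()].
#' @param control A [mee_control()] list.
#' @return An object of class `"mee_fit"` with components `weights` (a
#'   [weight_parameters()]), `objective`, `fitted`, `measured`,
#'   `residuals` (all per stride), `constraints` (the [mee_constraints()]
#'   report at the optimum), `convergence` (per-start table, seed,
#'   status) and `data` (the prepared statistics). Methods: `print`,
#'   `summary`, `coef`, `fitted`, `residuals`, `predict`, `plot`,
#'   `simulate`.
#' @export
fit_mee <- function(dataset, control = mee_control()) {
  stopifnot(inherits(dataset, "estimation_dataset"))
  prep <- prepare_estimation(dataset)
  ws <- control$wscale
  base_starts <- list(rep(0, 10L), as_weight_vector(published_weights()) / ws)
  n_extra <- max(0L, control$multistart - length(base_starts))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(control$seed)
  extra <- lapply(seq_len(n_extra), function(i) {
    base_starts[[1L + (i %% 2L)]] + stats::rnorm(10L, 0, control$start_sd)
  })
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  starts <- c(base_starts, extra)[seq_len(max(1L, control$multistart))]
  runs <- suppressWarnings(lapply(starts, function(z0) {
    r <- al_solve(prep, z0, control)
    r$w <- repair_feasibility(prep, r$w)
    g <- constraint_eval(prep, r$w)
    r$violation <- max(0, -min(g))
    r$objective <- sum((prep$strides$measured -
                          model_stride_average(prep, r$w))^2) /
      (2 * nrow(prep$strides))
    r
  }))
  tab <- data.frame(start = seq_along(runs),
                    objective = vapply(runs, `[[`, numeric(1L), "objective"),
                    violation = vapply(runs, `[[`, numeric(1L), "violation"),
                    status = vapply(runs, `[[`, character(1L), "status"))
  feasible <- tab$violation <= control$tol_con
  if (!any(feasible)) {
    best_bad <- runs[[which.min(tab$violation)]]
    rep_con <- suppressWarnings(mee_constraints(best_bad$w, prep))
    stop("fit_mee: no feasible solution from any start; worst margins: ",
         paste(names(rep_con$worst), signif(rep_con$worst, 3),
               sep = "=", collapse = ", "), call. = FALSE)
  }
  best <- runs[[which(feasible)[which.min(tab$objective[feasible])]]]
  wv <- best$w
  weights <- weight_parameters(wv[1:5], wv[6:10],
                               provenance = sprintf("fit-seed%d", control$seed))
  fitted <- model_stride_average(prep, wv)
  constraints <- suppressWarnings(mee_constraints(wv, prep))
  structure(list(weights = weights,
                 objective = best$objective,
                 fitted = fitted,
                 measured = prep$strides$measured,
                 residuals = prep$strides$measured - fitted,
                 constraints = constraints,
                 convergence = list(starts = tab, best_start = which(feasible)[
                   which.min(tab$objective[feasible])],
                   status = best$status, seed = control$seed),
                 control = control,
                 data = prep,
                 call = match.call()),
            class = "mee_fit")
}

#' @export
print.mee_fit <- function(x, ...) {
  cat("Constrained NLS fit of joint-space heat-coefficient weights\n")
  cat(sprintf("  strides: %d, objective: %.6g W^2, RMS residual: %.3f W\n",
              length(x$fitted), x$objective,
              sqrt(mean(x$residuals^2))))
  print(x$weights)
  cat("  worst constraint margins:\n")
  print(signif(x$constraints$worst, 3))
  invisible(x)
}

#' @export
summary.mee_fit <- function(object, ...) {
  pe <- 100 * abs(object$residuals) / object$measured
  r2 <- if (stats::sd(object$fitted) > 0 && stats::sd(object$measured) > 0) {
    stats::cor(object$fitted, object$measured)^2
  } else NA_real_
  out <- list(weights = object$weights, objective = object$objective,
              rms_W = sqrt(mean(object$residuals^2)),
              mean_abs_pct_error = mean(pe), sd_abs_pct_error = stats::sd(pe),
              r_squared = r2, worst_margins = object$constraints$worst,
              convergence = object$convergence)
  class(out) <- "summary.mee_fit"
  out
}

#' @export
print.summary.mee_fit <- function(x, ...) {
  print(x$weights)
  cat(sprintf("objective %.6g W^2 | RMS %.3f W | abs error %.2f +/- %.2f %% | R^2 %.4f\n",
              x$objective, x$rms_W, x$mean_abs_pct_error, x$sd_abs_pct_error,
              x$r_squared))
  cat("worst margins:\n"); print(signif(x$worst_margins, 3))
  invisible(x)
}

#' @export
coef.mee_fit <- function(object, ...) {
  c(object$weights$am, object$weights$sl)
}

#' @export
fitted.mee_fit <- function(object, ...) object$fitted

#' @export
residuals.mee_fit <- function(object, ...) object$residuals

#' Predict stride-average MEE for new data
#'
#' @param object A fitted `"mee_fit"`.
#' @param newdata An [estimation_dataset()] (its `measured` values are
#'   ignored); default: the training data.
#' @param ... Unused.
#' @return Numeric vector of model stride-average MEE rates in W.
#' @export
predict.mee_fit <- function(object, newdata = NULL, ...) {
  wv <- as_weight_vector(object$weights)
  prep <- if (is.null(newdata)) object$data else prepare_estimation(newdata)
  model_stride_average(prep, wv)
}

#' @export
plot.mee_fit <- function(x, ...) {
  graphics::plot(x$measured, x$fitted,
                 xlab = "measured mean MEE rate (W)",
                 ylab = "model mean MEE rate (W)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate measured stride averages from a fitted model
#'
#' Draws synthetic "measured" mean MEE rates around the fitted values with
#' multiplicative Gaussian noise whose relative standard deviation is
#' taken from the fit residuals (or given).
#'
#' @param object A `"mee_fit"`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed.
#' @param sd_rel Relative noise SD; default the residual relative SD.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of simulated measurements.
#' @export
simulate.mee_fit <- function(object, nsim = 1, seed = NULL, sd_rel = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sd_rel)) sd_rel <- stats::sd(object$residuals / object$fitted)
  out <- replicate(nsim, object$fitted *
                     (1 + stats::rnorm(length(object$fitted), 0, sd_rel)))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Validate weights against measured data
#'
#' Evaluates the model with fixed weights on a validation dataset and
#' reports per-stride percent errors, their mean and SD, the
#' inter-subject coefficient of determination (squared correlation of
#' model versus measured over all strides) and per-subject intra-subject
#' R-squared values.
#'
#' @param w A [weight_parameters()] object or numeric vector of length 10.
#' @param dataset An [estimation_dataset()] with measured values.
#' @return An object of class `"mee_validation"`: list with `table`
#'   (per-stride subject, speed, measured, model, pct_error),
#'   `mean_abs_pct_error`, `sd_abs_pct_error`, `r_squared_inter`,
#'   `r_squared_intra` (named per subject, NA-flagged when undefined).
#' @export
validate_mee <- function(w, dataset) {
  prep <- prepare_estimation(dataset)
  wv <- as_weight_vector(w)
  model <- model_stride_average(prep, wv)
  st <- prep$strides
  ids <- vapply(prep$subjects, `[[`, character(1L), "id")
  tab <- data.frame(subject = ids[st$subject], speed = st$speed,
                    measured = st$measured, model = model,
                    pct_error = 100 * abs(model - st$measured) / st$measured)
  inter <- if (nrow(tab) >= 2L && stats::sd(tab$measured) > 0 &&
               stats::sd(tab$model) > 0) {
    stats::cor(tab$model, tab$measured)^2
  } else NA_real_
  intra <- vapply(split(tab, tab$subject), function(d) {
    if (nrow(d) >= 2L && stats::sd(d$measured) > 0 && stats::sd(d$model) > 0) {
      stats::cor(d$model, d$measured)^2
    } else NA_real_
  }, numeric(1L))
  structure(list(table = tab,
                 mean_abs_pct_error = mean(tab$pct_error),
                 sd_abs_pct_error = stats::sd(tab$pct_error),
                 r_squared_inter = inter,
                 r_squared_intra = intra),
            class = "mee_validation")
}

#' @export
print.mee_validation <- function(x, ...) {
  cat(sprintf("Validation: %d stride(s), abs error %.2f +/- %.2f %%, inter-subject R^2 %.4f\n",
              nrow(x$table), x$mean_abs_pct_error, x$sd_abs_pct_error,
              x$r_squared_inter))
  cat("  intra-subject R^2:", paste(names(x$r_squared_intra),
                                    signif(x$r_squared_intra, 3),
                                    sep = "=", collapse = ", "), "\n")
  invisible(x)
}
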