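#' Convert respiratory gas exchange to metabolic power
#'
#' Converts per-minute oxygen uptake (and carbon dioxide output) to watts.
#' `"brockway"` uses the gas-exchange energy equation
#' \eqn{(16.58\,\dot{V}O_2 + 4.51\,\dot{V}CO_2)} kJ/min (urinary nitrogen
#' term dropped, as urine is not collected in a treadmill protocol);
#' `"fixed_equivalent"` multiplies \eqn{\dot{V}O_2} by a single energy
#' equivalent of oxygen (default 20.1 kJ/L). The two agree to within a few
#' percent for respiratory exchange ratios (RER) in the aerobic range; a
#' RER at or above 1 invalidates the equivalence and raises a warning, and
#' the per-minute validity is attached as attribute `rer_valid`.
#'
#' @param vo2 Oxygen uptake, L O2/min (vectorised).
#' @param vco2 Carbon dioxide output, L CO2/min (required for
#'   `"brockway"`, used only for the RER check otherwise).
#' @param method `"brockway"` or `"fixed_equivalent"`.
#' @param energy_equivalent Energy equivalent of oxygen, kJ/L, for
#'   `"fixed_equivalent"`.
#' @return Metabolic power in W, with attribute `rer_valid`.
#' @examples
#' vo2_to_watts(0.3, 0.255)  # about 102.1 W at RER 0.85
#' @export
vo2_to_watts <- function(vo2, vco2 = NULL,
                         method = c("brockway", "fixed_equivalent"),
                         energy_equivalent = 20.1) {
  method <- match.arg(method)
  if (any(vo2 < 0)) stop("vo2_to_watts: vo2 must be non-negative", call. = FALSE)
  if (method == "brockway") {
    if (is.null(vco2)) stop("vo2_to_watts: brockway needs vco2", call. = FALSE)
    if (any(vco2 < 0)) stop("vo2_to_watts: vco2 must be non-negative", call. = FALSE)
    kj_min <- 16.58 * vo2 + 4.51 * vco2
  } else {
    kj_min <- energy_equivalent * vo2
  }
  watts <- kj_min * 1000 / 60
  rer_valid <- rep(TRUE, length(vo2))
  if (!is.null(vco2)) {
    rer <- ifelse(vo2 > 0, vco2 / vo2, NA_real_)
    rer_valid <- is.na(rer) | rer < 1
    if (any(!rer_valid)) {
      warning("vo2_to_watts: RER >= 1 in ", sum(!rer_valid),
              " minute(s); aerobic conversion validity violated", call. = FALSE)
    }
  }
  attr(watts, "rer_valid") <- rer_valid
  watts
}

#' Basal metabolic rate from a resting record
#'
#' The BMR is measured during quiet sitting over a six-minute interval;
#' the mean of the watt-converted last three minutes of that interval
#' (minutes 4-6) is taken, so that the initial settling minutes are
#' excluded.
#'
#' @param record Data frame with per-minute columns `vo2`, `vco2`
#'   (L/min), at least 6 rows in time order.
#' @param method,energy_equivalent Passed to [vo2_to_watts()].
#' @return BMR in W.
#' @export
compute_bmr <- function(record, method = "brockway", energy_equivalent = 20.1) {
  if (nrow(record) < 6L) {
    stop("compute_bmr: need at least 6 rest minutes, got ", nrow(record),
         call. = FALSE)
  }
  idx <- 4:6
  w <- vo2_to_watts(record$vo2[idx], record$vco2[idx], method = method,
                    energy_equivalent = energy_equivalent)
  mean(w)
}

#' Representative MEE for one walking speed
#'
#' Each five-minute treadmill condition yields five per-minute gas
#' measurements; the representative metabolic rate is the mean of the
#' watt-converted last three minutes (minutes 3-5), excluding the
#' transient first two minutes.
#'
#' @param record Data frame with per-minute columns `vo2`, `vco2` for one
#'   speed condition.
#' @param n_minutes Expected record length (default 5); set `NULL` to
#'   accept any record with at least 3 minutes and use its last three.
#' @param method,energy_equivalent Passed to [vo2_to_watts()].
#' @return Representative MEE in W.
#' @export
representative_mee <- function(record, n_minutes = 5L, method = "brockway",
                               energy_equivalent = 20.1) {
  n <- nrow(record)
  if (!is.null(n_minutes) && n != n_minutes) {
    stop("representative_mee: expected ", n_minutes, " minutes, got ", n,
         call. = FALSE)
  }
  if (n < 3L) stop("representative_mee: need at least 3 minutes", call. = FALSE)
  idx <- (n - 2L):n
  w <- vo2_to_watts(record$vo2[idx], record$vco2[idx], method = method,
                    energy_equivalent = energy_equivalent)
  mean(w)
}

#' Read a metabolic record CSV
#'
#' Columns: `minute`, `condition`, `vo2_L_min`, `vco2_L_min`. Returns a
#' list of per-condition data frames with columns `minute`, `vo2`, `vco2`.
#'
#' @param path CSV path.
#' @return Named list of per-condition records, in file order.
#' @export
read_metabolic <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("minute", "condition", "vo2_L_min", "vco2_L_min")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("read_metabolic: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, factor(df$condition, levels = unique(df$condition))),
                function(d) data.frame(minute = d$minute, vo2 = d$vo2_L_min,
                                       vco2 = d$vco2_L_min))
  out
}
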