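#' Heat-coefficient weight parameters
#'
#' The ten dimensionless regression weights of the separable heat
#' coefficient functions: five for the activation-maintenance coefficient
#' \eqn{h^{am}} and five for the shortening-lengthening coefficient
#' \eqn{h^{sl}}. The first four weights of each set multiply the normalized
#' subject parameters (intercept, mass, age, height); the fifth multiplies
#' the subject- and DOF-specific normalized strength term.
#'
#' @param am Numeric vector of length 5: \eqn{(w_0^{am}, \ldots, w_4^{am})}.
#' @param sl Numeric vector of length 5: \eqn{(w_0^{sl}, \ldots, w_4^{sl})}.
#' @param provenance Label recording where the weights came from.
#' @param scales Normalization scales the weights were estimated under.
#' @return An object of class `"weight_parameters"`.
#' @seealso [published_weights()]
#' @export
weight_parameters <- function(am, sl, provenance = "user",
                              scales = list(mass = 100, age = 100,
                                            height = 10, torque = 100)) {
  am <- as.numeric(am); sl <- as.numeric(sl)
  if (length(am) != 5L || length(sl) != 5L || !all(is.finite(c(am, sl)))) {
    stop("weight_parameters: 'am' and 'sl' must be finite numeric vectors of length 5",
         call. = FALSE)
  }
  names(am) <- paste0("w", 0:4, "_am")
  names(sl) <- paste0("w", 0:4, "_sl")
  structure(list(am = am, sl = sl, scales = scales,
                 provenance = as.character(provenance)),
            class = "weight_parameters")
}

#' Published weight parameter estimates
#'
#' Returns the packaged published estimates of the ten weight parameters
#' (constrained nonlinear least squares on treadmill walking of eight
#' adults at five speeds), stored verbatim in
#' `extdata/table2.json`.
#'
#' @return A [weight_parameters()] object with provenance
#'   `"published-Table2"`.
#' @examples
#' w <- published_weights()
#' w$am
#' @export
published_weights <- function() {
  path <- system.file("extdata", "table2.json", package = "gaitmee")
  if (!nzchar(path)) stop("packaged weights fixture not found", call. = FALSE)
  read_weights(path)
}

#' Read weight parameters from JSON
#'
#' Expects keys `am` (5 floats), `sl` (5 floats), optional `scales` and
#' `provenance`.
#'
#' @param path Path to a weights JSON file.
#' @return A [weight_parameters()] object.
#' @export
read_weights <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scales <- if (!is.null(x$scales)) as.list(x$scales) else
    list(mass = 100, age = 100, height = 10, torque = 100)
  weight_parameters(x$am, x$sl,
                    provenance = if (!is.null(x$provenance)) x$provenance else "file",
                    scales = scales)
}

#' Write weight parameters to JSON
#'
#' @param w A [weight_parameters()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path) {
  stopifnot(inherits(w, "weight_parameters"))
  jsonlite::write_json(list(am = unname(w$am), sl = unname(w$sl),
                            scales = w$scales, provenance = w$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.weight_parameters <- function(x, ...) {
  cat("Heat-coefficient weights (", x$provenance, ")\n", sep = "")
  cat("  am:", format(x$am, digits = 3), "\n")
  cat("  sl:", format(x$sl, digits = 3), "\n")
  invisible(x)
}
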