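#' Parameters of the negative-autoregulation model
#'
#' Container for the kinetic parameters of the self-repression ODE
#' \deqn{dm/dt = c\,\beta \frac{K^n}{m^n + K^n} - \gamma m,}
#' where \eqn{m} is the transcript concentration. `n = Inf` selects the
#' step-function (Heaviside) limit in which production switches off
#' completely above the repression threshold `K`; `K = Inf` encodes a gene
#' with no self-repression at all (production is always maximal).
#'
#' @param beta Production rate per gene copy (intensity units per time);
#'   must be positive.
#' @param gamma First-order mRNA degradation rate (per time); must be
#'   positive.
#' @param K Repression threshold: the concentration at which production is
#'   half-maximal (finite Hill) or shuts off (step limit). Positive; `Inf`
#'   means no repression.
#' @param n Hill coefficient (cooperativity of repression). Positive, or
#'   `Inf` for the step-function limit.
#' @param c Gene copy number, 1 or 2.
#'
#' @return An object of class `model_params` (a validated list with fields
#'   `beta`, `gamma`, `K`, `n`, `c`).
#' @examples
#' p <- model_params(beta = 1, gamma = 1, K = 0.5, n = 4, c = 2)
#' steady_state_hill(p)
#' @export
model_params <- function(beta, gamma, K, n, c = 1L) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta), beta > 0)
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma), gamma > 0)
  stopifnot(is.numeric(K), length(K) == 1L, K > 0)          # Inf allowed
  stopifnot(is.numeric(n), length(n) == 1L, n > 0)          # Inf allowed
  c <- as.integer(c)
  if (!c %in% c(1L, 2L)) stop("copy number `c` must be 1 or 2")
  structure(
    list(beta = beta, gamma = gamma, K = K, n = n, c = c),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "model_params: beta=%g gamma=%g K=%s n=%s c=%d (beta/gamma per copy = %g)\n",
    x$beta, x$gamma,
    if (is.infinite(x$K)) "Inf (no repression)" else format(x$K),
    if (is.infinite(x$n)) "Inf (step limit)" else format(x$n),
    x$c, x$beta / x$gamma
  ))
  invisible(x)
}

#' Replace the copy number of a parameter set
#'
#' @param p A `model_params` object.
#' @param c New copy number (1 or 2).
#' @return A `model_params` object identical to `p` except for `c`.
#' @export
with_copies <- function(p, c) {
  model_params(p$beta, p$gamma, p$K, p$n, c)
}

# ---- JSON round trip -------------------------------------------------------

inf_to_json <- function(x) if (is.infinite(x)) "inf" else x
inf_from_json <- function(x) {
  if (is.character(x)) {
    if (!identical(tolower(x), "inf")) stop("unrecognized sentinel: ", x)
    return(Inf)
  }
  as.numeric(x)
}

#' Serialize model objects to JSON
#'
#' `model_params`, `hill_solution` and `category_result` objects round-trip
#' through JSON; infinite values (the step-limit Hill coefficient, absent
#' thresholds, one-sided bounds) are encoded as the string `"inf"`.
#'
#' @param x A `model_params`, `hill_solution` or `category_result` object.
#' @return A JSON string.
#' @seealso [params_from_json()]
#' @export
params_to_json <- function(x) {
  stopifnot(inherits(x, c("model_params", "hill_solution", "category_result")))
  lst <- unclass(x)
  lst <- lapply(lst, function(v) if (is.numeric(v)) inf_to_json(v) else v)
  lst$.class <- class(x)[1L]
  jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Deserialize model objects from JSON
#'
#' @param json A JSON string produced by [params_to_json()].
#' @return The reconstructed object, with its original class.
#' @export
params_from_json <- function(json) {
  lst <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  cls <- lst$.class
  lst$.class <- NULL
  num_fields <- c("beta", "gamma", "K", "n", "x", "beta_over_gamma",
                  "K_est", "bg_est", "m1", "m2", "rho")
  for (f in intersect(names(lst), num_fields)) {
    lst[[f]] <- inf_from_json(lst[[f]])
  }
  if (identical(cls, "model_params")) {
    return(model_params(lst$beta, lst$gamma, lst$K, lst$n, lst$c))
  }
  structure(lst, class = cls)
}
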