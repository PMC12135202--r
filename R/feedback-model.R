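#' @title Steady-state analysis of transcriptional negative autoregulation
#' @description
#' The model is a single ODE for the transcript concentration \eqn{m} of a
#' self-repressing gene present in \eqn{c} copies:
#' \deqn{dm/dt = c\beta \frac{K^n}{m^n + K^n} - \gamma m
#'   \quad\Longleftrightarrow\quad
#'   dm/dt = \frac{c\beta}{(m/K)^n + 1} - \gamma m.}
#' As the Hill coefficient \eqn{n \to \infty} the repression term becomes a
#' Heaviside step: production is \eqn{c\beta} below the threshold \eqn{K} and
#' zero above it, so the steady state sits either at \eqn{m = K} (repressed)
#' or at \eqn{m = c\beta/\gamma} (unrepressed). Comparing the steady state at
#' one versus two gene copies then reads out whether feedback is engaged:
#' the 1-to-2-copy ratio is 1/2 without feedback and approaches 1 under
#' strong compensation.
#' @name feedback_model
NULL

new_steady_state <- function(m_ss, regime, c) {
  structure(list(m_ss = m_ss, regime = regime, c = as.integer(c)),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady_state: m_ss=%g (%s, c=%d)\n", x$m_ss, x$regime, x$c))
  invisible(x)
}

#' Hill-repressed production rate
#'
#' Evaluates the production term \eqn{c\beta K^n/(m^n + K^n)} of the
#' negative-autoregulation ODE. The equivalent algebraic form
#' \eqn{c\beta/((m/K)^n + 1)} is used internally for numerical stability at
#' large `n`; the two forms agree to relative tolerance 1e-12.
#'
#' @param m Transcript concentration (non-negative scalar or vector).
#' @param p A [model_params()] object with finite Hill coefficient.
#' @return Production rate(s), same length as `m`.
#' @examples
#' p <- model_params(1, 1, K = 0.5, n = 4, c = 2)
#' hill_production(1, p)  # 2/(1 + 16)
#' @export
hill_production <- function(m, p) {
  stopifnot(inherits(p, "model_params"), is.finite(p$n))
  if (any(m < 0)) stop("transcript concentration `m` must be non-negative")
  if (is.infinite(p$K)) return(rep(p$c * p$beta, length(m)))
  p$c * p$beta / ((m / p$K)^p$n + 1)
}

ode_rhs <- function(m, p) {
  prod <- if (is.infinite(p$n)) {
    # Heaviside limit, theta(0) = 1: repression active exactly at m = K
    if (m >= p$K) 0 else p$c * p$beta
  } else {
    hill_production(m, p)
  }
  prod - p$gamma * m
}

#' Integrate the autoregulation ODE
#'
#' Fixed-step 4th-order Runge-Kutta integration of the Hill-repression ODE.
#' For any positive initial condition the trajectory converges monotonically
#' to the unique steady state (the right-hand side is strictly decreasing in
#' `m`), which makes this a useful numerical cross-check on
#' [steady_state_hill()].
#'
#' @param p A [model_params()] object with finite `n`.
#' @param m0 Initial concentration (non-negative).
#' @param t_end Final time (positive).
#' @param dt Step size (positive).
#' @return A data.frame with columns `t` and `m`.
#' @export
integrate_ode <- function(p, m0, t_end, dt) {
  stopifnot(inherits(p, "model_params"), m0 >= 0, t_end > 0, dt > 0)
  times <- seq(0, t_end, by = dt)
  m <- numeric(length(times))
  m[1] <- m0
  for (i in seq_along(times)[-1]) {
    mi <- m[i - 1]
    k1 <- ode_rhs(mi, p)
    k2 <- ode_rhs(max(mi + dt / 2 * k1, 0), p)
    k3 <- ode_rhs(max(mi + dt / 2 * k2, 0), p)
    k4 <- ode_rhs(max(mi + dt * k3, 0), p)
    m[i] <- mi + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (m[i] < 0) {
      stop("step-size instability: trajectory became negative; reduce dt")
    }
  }
  data.frame(t = times, m = m)
}

#' Steady state of the Hill-repression model
#'
#' Solves \eqn{c\beta/(1 + (m/K)^n) = \gamma m} for the unique positive
#' root. The left side is strictly decreasing and the right side strictly
#' increasing in `m`, so a single root exists in \eqn{(0, c\beta/\gamma]};
#' it is found by bisection to absolute tolerance 1e-10.
#'
#' @param p A [model_params()] object with finite `n` (use
#'   [steady_state_step()] for the `n = Inf` limit). An infinite `K` (no
#'   repression) returns the unrepressed level \eqn{c\beta/\gamma}.
#' @return A `steady_state` object (fields `m_ss`, `regime`, `c`). The
#'   regime label compares the unrepressed level \eqn{c\beta/\gamma} with
#'   `K`, matching the step-limit classification.
#' @examples
#' steady_state_hill(model_params(1, 1, K = 0.5, n = 4, c = 1))  # m = 0.5
#' @export
steady_state_hill <- function(p, tol = 1e-10) {
  stopifnot(inherits(p, "model_params"), is.finite(p$n))
  upper <- p$c * p$beta / p$gamma
  if (is.infinite(p$K)) {
    return(new_steady_state(upper, "unrepressed", p$c))
  }
  g <- function(m) p$c * p$beta / ((m / p$K)^p$n + 1) - p$gamma * m
  lo <- 0
  hi <- upper
  # g(0) = c beta > 0, g(upper) <= 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  m_ss <- (lo + hi) / 2
  regime <- if (upper > p$K) "repressed" else if (upper < p$K) "unrepressed" else "boundary"
  new_steady_state(m_ss, regime, p$c)
}

#' Steady state of the step-function (Heaviside) limit
#'
#' In the \eqn{n \to \infty} limit production is all-or-none: if the
#' unrepressed level \eqn{c\beta/\gamma} exceeds the threshold `K` the
#' steady state is pinned at \eqn{m = K} (repressed); if it falls below,
#' repression never engages and \eqn{m = c\beta/\gamma}. At exact equality
#' the two coincide and the regime is labeled `"boundary"`. The Heaviside
#' convention \eqn{\theta(0) = 1} makes \eqn{m = K} a fixed point.
#'
#' @param p A [model_params()] object with `n = Inf`.
#' @return A `steady_state` object.
#' @examples
#' steady_state_step(model_params(1.2, 1, K = 1, n = Inf, c = 2))  # m = 1
#' @export
steady_state_step <- function(p) {
  stopifnot(inherits(p, "model_params"), is.infinite(p$n))
  unrep <- p$c * p$beta / p$gamma
  if (is.infinite(p$K)) return(new_steady_state(unrep, "unrepressed", p$c))
  if (unrep > p$K) {
    new_steady_state(p$K, "repressed", p$c)
  } else if (unrep < p$K) {
    new_steady_state(unrep, "unrepressed", p$c)
  } else {
    new_steady_state(p$K, "boundary", p$c)
  }
}

steady_state_auto <- function(p) {
  if (is.infinite(p$n)) steady_state_step(p) else steady_state_hill(p)
}

#' Model-predicted 1-to-2-copy dosage ratio
#'
#' Solves the steady state at one and at two gene copies (all other
#' parameters shared) and returns their ratio \eqn{m_1/m_2}. Negative
#' autoregulation compresses this ratio from 1/2 (no feedback, `K = Inf`)
#' toward 1 (full compensation); it always lies in \eqn{[0.5, 1]}.
#'
#' @param p A [model_params()] object; the `c` field is ignored.
#' @return The scalar ratio \eqn{m_1/m_2}.
#' @export
dosage_ratio_model <- function(p) {
  m1 <- steady_state_auto(with_copies(p, 1L))$m_ss
  m2 <- steady_state_auto(with_copies(p, 2L))$m_ss
  m1 / m2
}

#' Minimal admissible Hill coefficient for a dosage ratio
#'
#' The closed-form inversion of the two-copy/one-copy steady states (see
#' [solve_hill_threshold()]) requires \eqn{1 - 2\rho^{n+1} > 0}. Solving for
#' `n` gives the smallest Hill coefficient compatible with an observed
#' ratio: \eqn{n_{\min} = \ln(1/2)/\ln(\rho) - 1}. Ratios close to 1 demand
#' very cooperative repression (e.g. \eqn{\rho = 0.98} requires
#' \eqn{n > 33.3}).
#'
#' @param rho Observed 1-to-2-copy ratio, strictly between 0.5 and 1.
#' @return The minimal Hill coefficient (scalar).
#' @export
min_hill_coefficient <- function(rho) {
  if (any(rho <= 0.5 | rho >= 1)) {
    stop("dosage ratio must lie strictly between 0.5 and 1")
  }
  log(0.5) / log(rho) - 1
}

#' Invert a dosage ratio into Hill-model parameters
#'
#' Given the normalized two-copy level \eqn{m_2}, the 1-to-2-copy ratio
#' \eqn{\rho = m_1/m_2} and an assumed Hill coefficient `n`, the two
#' steady-state equations
#' \deqn{2\beta/\gamma = m_2(1 + (m_2/K)^n), \quad
#'       \beta/\gamma = m_1(1 + (m_1/K)^n)}
#' are solved in closed form. Writing \eqn{x = (m_2/K)^n}, their ratio gives
#' \eqn{x = (2\rho - 1)/(1 - 2\rho^{n+1})}, hence
#' \eqn{K = m_2\, x^{-1/n}} and
#' \eqn{\beta/\gamma = m_2 \rho\,(1 + \rho^n x)}.
#' The solution exists (is "admissible") only when the denominator is
#' positive, i.e. when `n` exceeds [min_hill_coefficient()] at this ratio;
#' otherwise the result is returned with `valid = FALSE` rather than as an
#' error.
#'
#' @param rho 1-to-2-copy ratio, strictly in (0.5, 1).
#' @param m2 Normalized two-copy steady-state level (positive).
#' @param n Hill coefficient to assume (positive, finite).
#' @return An object of class `hill_solution` with fields `K`,
#'   `beta_over_gamma`, `x`, `n`, `valid`.
#' @examples
#' s <- solve_hill_threshold(rho = 0.816, m2 = 0.613, n = 4)
#' s$K               # ~0.50
#' s$beta_over_gamma # ~1.0
#' @export
solve_hill_threshold <- function(rho, m2, n) {
  if (rho <= 0.5 || rho >= 1) {
    stop("dosage ratio must lie strictly between 0.5 and 1 for a finite-n solution")
  }
  stopifnot(m2 > 0, n > 0, is.finite(n))
  denom <- 1 - 2 * rho^(n + 1)
  if (denom <= 0) {
    return(structure(
      list(K = NA_real_, beta_over_gamma = NA_real_, x = NA_real_,
           n = n, valid = FALSE),
      class = "hill_solution"
    ))
  }
  x <- (2 * rho - 1) / denom
  K <- m2 * x^(-1 / n)
  bg <- m2 * rho * (1 + rho^n * x)
  structure(
    list(K = K, beta_over_gamma = bg, x = x, n = n, valid = TRUE),
    class = "hill_solution"
  )
}

#' @export
print.hill_solution <- function(x, ...) {
  if (!x$valid) {
    cat(sprintf("hill_solution: no admissible solution at n=%g\n", x$n))
  } else {
    cat(sprintf("hill_solution: K=%g beta/gamma=%g (n=%g, x=%g)\n",
                x$K, x$beta_over_gamma, x$n, x$x))
  }
  invisible(x)
}

#' Solve mutant-condition Hill parameters given the control solution
#'
#' Infers the Hill coefficient and repression threshold of a mutant
#' genotype from its normalized 1- and 2-copy levels, anchored to the
#' control's inferred net production rate. Under the default
#' `"shared_bg"` assumption (mutant \eqn{\beta/\gamma} equals the
#' control's value \eqn{b}) the mutant steady-state equations reduce in
#' closed form: \eqn{x = 2b/m_2 - 1},
#' \eqn{n = \ln((b/m_1 - 1)/x)/\ln(m_1/m_2)}, \eqn{K = m_2 x^{-1/n}}.
#' The alternative `"shared_K"` assumption fixes the mutant threshold to
#' the control's `K` and root-finds `n` (then \eqn{\beta/\gamma}) instead.
#' In both modes the result is verified by forward steady-state solves;
#' inconsistent inputs (e.g. a near-0.5 ratio incompatible with any
#' positive `n`) return `valid = FALSE` with a message, not an error.
#'
#' @param control A valid `hill_solution` for the control genotype.
#' @param mutant_m1,mutant_m2 Mutant 1- and 2-copy mean levels, normalized
#'   by the control 2-copy mean.
#' @param assumption `"shared_bg"` (default) or `"shared_K"`.
#' @return A list with fields `n_mut`, `K_mut`, `bg_mut`, `valid`,
#'   `message`, `max_residual`.
#' @export
solve_mutant_hill <- function(control, mutant_m1, mutant_m2,
                              assumption = c("shared_bg", "shared_K")) {
  stopifnot(inherits(control, "hill_solution"), isTRUE(control$valid),
            mutant_m1 > 0, mutant_m2 > 0, mutant_m1 < mutant_m2)
  assumption <- match.arg(assumption)
  r <- mutant_m1 / mutant_m2
  fail <- function(msg) list(n_mut = NA_real_, K_mut = NA_real_,
                             bg_mut = NA_real_, valid = FALSE,
                             message = msg, max_residual = NA_real_)

  if (assumption == "shared_bg") {
    b <- control$beta_over_gamma
    x <- 2 * b / mutant_m2 - 1
    a <- b / mutant_m1 - 1
    if (x <= 0 || a <= 0) {
      return(fail("no admissible solution: mutant levels exceed shared production"))
    }
    if (a / x >= 1) {
      return(fail("no admissible solution: implied Hill coefficient is not positive"))
    }
    n_mut <- log(a / x) / log(r)
    K_mut <- mutant_m2 * x^(-1 / n_mut)
    bg_mut <- b
  } else {
    K_mut <- control$K
    h <- function(n) {
      mutant_m2 * (1 + (mutant_m2 / K_mut)^n) -
        2 * mutant_m1 * (1 + (mutant_m1 / K_mut)^n)
    }
    # h need not be monotone in n (e.g. both levels below K): scan a log
    # grid for a sign change and fall back to polishing the |h| minimum
    grid <- exp(seq(log(1e-3), log(500), length.out = 400))
    hv <- vapply(grid, h, numeric(1))
    sgn <- which(hv[-1] * hv[-length(hv)] <= 0)
    n_mut <- if (length(sgn) > 0) {
      stats::uniroot(h, grid[c(sgn[1], sgn[1] + 1)], tol = 1e-12)$root
    } else {
      stats::optimize(function(n) abs(h(n)),
                      grid[pmax(1, pmin(length(grid),
                                        which.min(abs(hv)) + c(-1, 1)))],
                      tol = 1e-12)$minimum
    }
    bg_mut <- mutant_m1 * (1 + (mutant_m1 / K_mut)^n_mut)
  }

  # forward verification: the inferred parameters must reproduce the inputs
  p1 <- model_params(beta = bg_mut, gamma = 1, K = K_mut, n = n_mut, c = 1L)
  res <- max(
    abs(steady_state_hill(p1)$m_ss - mutant_m1),
    abs(steady_state_hill(with_copies(p1, 2L))$m_ss - mutant_m2)
  )
  if (!is.finite(res) || res > 1e-6) {
    return(fail("no admissible solution: forward check failed"))
  }
  list(n_mut = n_mut, K_mut = K_mut, bg_mut = bg_mut, valid = TRUE,
       message = "ok", max_residual = res)
}

#' Categorize a genotype by its 1-to-2-copy ratio
#'
#' Three regimes of the step-function model: category 1 (ratio >= 0.9),
#' both copy numbers repressed, steady states at `K`; category 2
#' (0.6 < ratio < 0.9), two copies repressed at `K`, one copy unrepressed
#' at \eqn{\beta/\gamma}; category 3 (ratio <= 0.6), repression never
#' engages, steady states at \eqn{2\beta/\gamma} and \eqn{\beta/\gamma}.
#' Ratios marginally above 1 (measurement noise, up to 1.1) are clipped to
#' 1 with a warning.
#'
#' @param rho Observed 1-to-2-copy ratio, in (0, 1.1].
#' @param thresholds Length-2 numeric: the category-1 and category-3
#'   boundaries (defaults 0.9 and 0.6, both inclusive).
#' @return Integer category, 1, 2 or 3.
#' @examples
#' categorize(0.98)  # 1
#' categorize(0.75)  # 2
#' categorize(0.52)  # 3
#' @export
categorize <- function(rho, thresholds = c(0.9, 0.6)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] > thresholds[2])
  if (rho <= 0) stop("dosage ratio must be positive")
  if (rho > 1.1) stop("dosage ratio above 1.1 is not a plausible measurement")
  if (rho > 1) {
    warning("dosage ratio ", format(rho), " > 1 clipped to 1")
    rho <- 1
  }
  if (rho >= thresholds[1]) 1L else if (rho <= thresholds[2]) 3L else 2L
}

new_category_result <- function(category, K_est, bg_est, K_is_bound,
                                bg_is_bound, note = "") {
  structure(
    list(category = as.integer(category), K_est = K_est, bg_est = bg_est,
         K_is_bound = K_is_bound, bg_is_bound = bg_is_bound, note = note),
    class = "category_result"
  )
}

#' @export
print.category_result <- function(x, ...) {
  fmt <- function(v, b) if (b) paste0("> ", format(v)) else format(v)
  cat(sprintf("category_result: category %d, K %s, beta/gamma %s%s\n",
              x$category, fmt(x$K_est, x$K_is_bound),
              fmt(x$bg_est, x$bg_is_bound),
              if (nzchar(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Step-function parameter inference for a categorized genotype
#'
#' Reads off `K` and \eqn{\beta/\gamma} (per copy) from the normalized 1-
#' and 2-copy levels using the geometry of the step-function steady state:
#' category 1 pins both levels at `K` (so \eqn{\beta/\gamma} is only
#' bounded below by `K`); category 2 pins the 2-copy level at `K` and the
#' 1-copy level at \eqn{\beta/\gamma}; category 3 leaves both unrepressed
#' (\eqn{m_2 = 2\beta/\gamma}, \eqn{m_1 = \beta/\gamma}), so `K` is only
#' bounded below by \eqn{m_2} and consistency requires \eqn{m_2 \approx
#' 2 m_1}.
#'
#' @param category Integer 1, 2 or 3 (from [categorize()]).
#' @param m1,m2 Normalized 1- and 2-copy mean levels (control 2-copy
#'   mean = 1). `m1` marginally above `m2` is clipped.
#' @param consistency_frac Category 3 only: warn when
#'   \eqn{|m_2 - 2 m_1| > } `consistency_frac` \eqn{\times m_2}.
#' @return A `category_result` object; bound estimates carry
#'   `*_is_bound = TRUE` and are lower bounds.
#' @examples
#' infer_step_params(1, m1 = 0.98, m2 = 1)  # control: K = 1
#' @export
infer_step_params <- function(category, m1, m2, consistency_frac = 0.15) {
  stopifnot(category %in% 1:3, m1 > 0, m2 > 0)
  if (m1 > m2) {
    warning("m1 > m2; clipping m1 to m2")
    m1 <- m2
  }
  if (category == 1L) {
    new_category_result(1L, K_est = m2, bg_est = m2,
                        K_is_bound = FALSE, bg_is_bound = TRUE)
  } else if (category == 2L) {
    new_category_result(2L, K_est = m2, bg_est = m1,
                        K_is_bound = FALSE, bg_is_bound = FALSE)
  } else {
    dev <- abs(m2 - 2 * m1)
    note <- sprintf("category-3 consistency |m2 - 2*m1| = %.4g", dev)
    if (dev > consistency_frac * m2) {
      warning("category-3 inconsistency: m2 deviates from 2*m1 by ",
              format(dev), " (", format(round(100 * dev / m2, 1)),
              "% of m2)")
    }
    new_category_result(3L, K_est = m2, bg_est = m1,
                        K_is_bound = TRUE, bg_is_bound = FALSE, note = note)
  }
}

#' Steady state without autoregulatory feedback
#'
#' The linear birth-death limit (no repression term): \eqn{m = c\beta/\gamma}.
#' The 1-to-2-copy ratio is exactly 1/2 for any production and degradation
#' rates — the null expectation against which dosage compensation is read.
#'
#' @param beta Production rate per copy (non-negative).
#' @param gamma Degradation rate (positive).
#' @param c Copy number (1 or 2).
#' @return A `steady_state` object with regime `"unrepressed"`.
#' @export
no_feedback_steady_state <- function(beta, gamma, c) {
  stopifnot(beta >= 0, gamma > 0, c %in% 1:2)
  new_steady_state(c * beta / gamma, "unrepressed", c)
}

#' Predict the effect of enhancer-promoter distance vs repression changes
#'
#' Scans the step-function model under two perturbations: scaling the
#' production rate `beta` (a pure distance effect — moving an enhancer
#' closer to the promoter raises the maximal production) and scaling the
#' threshold `K` (a change in repression). As long as the scaled
#' \eqn{2\beta/\gamma} stays above the scaled `K`, increasing `beta` alone
#' leaves the repressed steady state pinned at \eqn{m = K}; only a change
#' in `K` moves it.
#'
#' @param p A [model_params()] object with `n = Inf`.
#' @param beta_scale,K_scale Positive multiplicative factors.
#' @return A list with `ss2`, `ss1` (steady states at 2 and 1 copies after
#'   scaling) and `ratio` (\eqn{m_1/m_2}).
#' @export
distance_effect_predict <- function(p, beta_scale = 1, K_scale = 1) {
  stopifnot(inherits(p, "model_params"), is.infinite(p$n),
            beta_scale > 0, K_scale > 0)
  ps <- model_params(p$beta * beta_scale, p$gamma, p$K * K_scale, Inf, p$c)
  ss2 <- steady_state_step(with_copies(ps, 2L))
  ss1 <- steady_state_step(with_copies(ps, 1L))
  list(ss2 = ss2, ss1 = ss1, ratio = ss1$m_ss / ss2$m_ss)
}

#' Error of the step-function approximation relative to a finite Hill fit
#'
#' Compares the parameters inferred from the same normalized levels
#' \eqn{(m_1, m_2)} by the closed-form finite-`n` inversion
#' ([solve_hill_threshold()]) and by the step-function rules
#' ([infer_step_params()]). Used to quantify how little is lost by working
#' in the \eqn{n \to \infty} limit: already at `n = 4` the relative
#' differences in `K` and \eqn{\beta/\gamma} are modest, and they vanish
#' as `n` grows.
#'
#' @param rho 1-to-2-copy ratio in (0.5, 1).
#' @param m2 Normalized 2-copy level.
#' @param n_finite Finite Hill coefficient to compare against.
#' @return A list: `valid`, the two (K, beta/gamma) pairs, and relative
#'   errors `rel_err_K`, `rel_err_bg` (step estimate as reference; `NA`
#'   where the step estimate is only a bound).
#' @export
hill_vs_step_error <- function(rho, m2, n_finite) {
  hill <- solve_hill_threshold(rho, m2, n_finite)
  if (!hill$valid) {
    return(list(valid = FALSE, rel_err_K = NA_real_, rel_err_bg = NA_real_))
  }
  m1 <- rho * m2
  step <- infer_step_params(categorize(rho), m1 = m1, m2 = m2)
  rel_err_K <- if (step$K_is_bound) NA_real_ else {
    abs(hill$K - step$K_est) / step$K_est
  }
  rel_err_bg <- if (step$bg_is_bound) NA_real_ else {
    abs(hill$beta_over_gamma - step$bg_est) / step$bg_est
  }
  list(valid = TRUE,
       K_hill = hill$K, bg_hill = hill$beta_over_gamma,
       K_step = step$K_est, bg_step = step$bg_est,
       K_step_is_bound = step$K_is_bound, bg_step_is_bound = step$bg_is_bound,
       rel_err_K = rel_err_K, rel_err_bg = rel_err_bg)
}
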