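# Unit tests for the ODE model core: production forms, steady states,
# closed-form inversion, categorization and step inference.

test_that("the two algebraic forms of the Hill production term agree", {
  eq1_form <- function(m, p) p$c * p$beta * p$K^p$n / (m^p$n + p$K^p$n)
  withr::with_seed(11, {
    for (i in 1:10000) {
      p <- model_params(beta = runif(1, 0.1, 3), gamma = runif(1, 0.1, 3),
                        K = runif(1, 0.05, 2), n = runif(1, 0.5, 12),
                        c = sample(1:2, 1))
      m <- runif(1, 0, 3)
      expect_equal(hill_production(m, p), eq1_form(m, p), tolerance = 1e-12)
    }
  })
  # spot values
  p <- model_params(1, 1, K = 0.5, n = 4, c = 2)
  expect_identical(hill_production(0, p), 2)                 # repressor absent
  expect_equal(hill_production(0.5, with_copies(p, 1L)), 0.5) # half-max at m = K
  expect_equal(hill_production(1, p), 2 / 17, tolerance = 1e-12)
  expect_error(hill_production(-0.1, p), "non-negative")
})

test_that("steady_state_hill finds the unique positive root", {
  # algebraic identity: c=1, beta=gamma=1, K=0.5, n=4 has root exactly 0.5
  ss <- steady_state_hill(model_params(1, 1, K = 0.5, n = 4, c = 1))
  expect_equal(ss$m_ss, 0.5, tolerance = 1e-9)
  # c=2 against the uniroot oracle (bisection vs Brent, dual route)
  ss2 <- steady_state_hill(model_params(1, 1, K = 0.5, n = 4, c = 2))
  expect_equal(ss2$m_ss, oracle_ss_hill(1, 1, 0.5, 4, 2), tolerance = 1e-8)
  # no repression limit
  ss3 <- steady_state_hill(model_params(1.3, 0.5, K = Inf, n = 4, c = 1))
  expect_equal(ss3$m_ss, 2.6)
  expect_identical(ss3$regime, "unrepressed")
  # residual is ~0 at the returned root
  g <- function(m, p) p$c * p$beta / (1 + (m / p$K)^p$n) - p$gamma * m
  p <- model_params(0.9, 1.4, K = 0.3, n = 7, c = 2)
  expect_lt(abs(g(steady_state_hill(p)$m_ss, p)), 1e-8)
})

test_that("steady_state_hill is monotone in beta, gamma and c", {
  withr::with_seed(12, {
    for (i in 1:20) {
      beta <- runif(1, 0.3, 2); gamma <- runif(1, 0.3, 2)
      K <- runif(1, 0.1, 1.5); n <- runif(1, 1, 10)
      base <- steady_state_hill(model_params(beta, gamma, K, n, 1))$m_ss
      expect_gt(steady_state_hill(model_params(beta * 1.5, gamma, K, n, 1))$m_ss, base)
      expect_lt(steady_state_hill(model_params(beta, gamma * 1.5, K, n, 1))$m_ss, base)
      expect_gte(steady_state_hill(model_params(beta, gamma, K, n, 2))$m_ss, base)
    }
  })
})

test_that("steady_state_step implements the Heaviside-limit geometry", {
  # cbeta/gamma > K: pinned at K, repressed
  ss <- steady_state_step(model_params(1.2, 1, K = 1, n = Inf, c = 2))
  expect_equal(ss$m_ss, 1)
  expect_identical(ss$regime, "repressed")
  # cbeta/gamma < K: unrepressed at beta/gamma
  ss1 <- steady_state_step(model_params(0.73, 1, K = 1, n = Inf, c = 1))
  expect_equal(ss1$m_ss, 0.73)
  expect_identical(ss1$regime, "unrepressed")
  # equality: boundary, theta(0) = 1 convention keeps m = K a fixed point
  ssb <- steady_state_step(model_params(1, 1, K = 1, n = Inf, c = 1))
  expect_equal(ssb$m_ss, 1)
  expect_identical(ssb$regime, "boundary")
})

test_that("Hill steady states converge monotonically to the step limit", {
  p_step <- model_params(1.2, 1, K = 0.8, n = Inf, c = 2)
  target <- steady_state_step(p_step)$m_ss
  errs <- vapply(c(4, 16, 64, 256), function(n) {
    abs(steady_state_hill(model_params(1.2, 1, 0.8, n, 2))$m_ss - target)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[4], 1e-2)
})

test_that("integrate_ode converges to the analytic steady state", {
  p <- model_params(1, 1, K = 0.5, n = 4, c = 2)
  ss <- steady_state_hill(p)$m_ss
  # fixed point: constant trajectory
  tc <- integrate_ode(p, m0 = ss, t_end = 5, dt = 0.01)
  expect_equal(max(abs(tc$m - ss)), 0, tolerance = 1e-8)
  # from zero: monotone approach, terminal value within 1e-6 (approx 0.613)
  tc0 <- integrate_ode(p, m0 = 0, t_end = 30, dt = 0.005)
  expect_true(all(diff(tc0$m) >= -1e-12))
  expect_equal(tail(tc0$m, 1), ss, tolerance = 1e-6)
  expect_equal(tail(tc0$m, 1), 0.613, tolerance = 1e-3)
  # from above: monotone decrease
  tc2 <- integrate_ode(p, m0 = 2, t_end = 30, dt = 0.005)
  expect_true(all(diff(tc2$m) <= 1e-12))
  expect_equal(tail(tc2$m, 1), ss, tolerance = 1e-6)
  # no repression: plain birth-death relaxation to beta/gamma
  pk <- model_params(1, 1, K = 1e9, n = 4, c = 1)
  expect_equal(tail(integrate_ode(pk, 0, 30, 0.005)$m, 1), 1, tolerance = 1e-6)
})

test_that("ODE terminal values agree with steady_state_hill across random params", {
  withr::with_seed(13, {
    for (i in 1:20) {
      p <- model_params(runif(1, 0.5, 2), runif(1, 0.5, 2),
                        K = runif(1, 0.2, 1.5), n = runif(1, 1, 8),
                        c = sample(1:2, 1))
      ss <- steady_state_hill(p)$m_ss
      tc <- integrate_ode(p, m0 = runif(1, 0, 2), t_end = 40 / p$gamma, dt = 0.005)
      expect_equal(tail(tc$m, 1), ss, tolerance = 1e-6)
    }
  })
})

test_that("dosage_ratio_model spans [0.5, 1] with the documented limits", {
  # no repression: exactly one half
  expect_equal(dosage_ratio_model(model_params(1.7, 0.6, K = Inf, n = Inf)), 0.5)
  expect_equal(dosage_ratio_model(model_params(1.7, 0.6, K = Inf, n = 4)), 0.5)
  # deep step repression: both copies pinned at K
  expect_equal(dosage_ratio_model(model_params(1.2, 1, K = 1, n = Inf)), 1)
  # finite Hill example
  expect_equal(dosage_ratio_model(model_params(1, 1, K = 0.5, n = 4)),
               0.5 / oracle_ss_hill(1, 1, 0.5, 4, 2), tolerance = 1e-7)
  # property: always within [0.5, 1]
  withr::with_seed(14, {
    for (i in 1:50) {
      pr <- random_hill_params()
      rho <- dosage_ratio_model(model_params(pr$beta, pr$gamma, pr$K, pr$n))
      expect_gte(rho, 0.5 - 1e-9)
      expect_lte(rho, 1 + 1e-9)
    }
  })
})

test_that("solve_hill_threshold inverts forward steady-state solves", {
  # worked example: parameters behind (rho ~ 0.8154, m2 ~ 0.6132)
  m2 <- oracle_ss_hill(1, 1, 0.5, 4, 2)
  sol <- solve_hill_threshold(rho = 0.5 / m2, m2 = m2, n = 4)
  expect_true(sol$valid)
  expect_equal(sol$K, 0.5, tolerance = 1e-6)
  expect_equal(sol$beta_over_gamma, 1, tolerance = 1e-6)
  # inadmissible: 2 * 0.98^21 > 1
  expect_false(solve_hill_threshold(0.98, 1, 20)$valid)
  # domain errors outside (0.5, 1)
  expect_error(solve_hill_threshold(0.5, 1, 4), "between 0.5 and 1")
  expect_error(solve_hill_threshold(1.0, 1, 4), "between 0.5 and 1")
  # barely-engaged repression: K far above m2
  weak <- solve_hill_threshold(0.5001, m2 = 1, n = 4)
  expect_true(weak$valid)
  expect_gt(weak$K, 5)
})

test_that("inversion round trip holds on a random admissible grid", {
  withr::with_seed(15, {
    done <- 0
    while (done < 200) {
      pr <- random_hill_params()
      m1 <- oracle_ss_hill(pr$beta, pr$gamma, pr$K, pr$n, 1)
      m2 <- oracle_ss_hill(pr$beta, pr$gamma, pr$K, pr$n, 2)
      rho <- m1 / m2
      if (rho <= 0.5 + 1e-6 || rho >= 1 - 1e-9) next
      sol <- solve_hill_threshold(rho, m2, pr$n)
      expect_true(sol$valid)
      expect_equal(sol$K, pr$K, tolerance = 1e-6)
      expect_equal(sol$beta_over_gamma, pr$beta / pr$gamma, tolerance = 1e-6)
      done <- done + 1
    }
  })
})

test_that("min_hill_coefficient marks the admissibility boundary exactly", {
  expect_equal(min_hill_coefficient(0.75), log(0.5) / log(0.75) - 1,
               tolerance = 1e-12)
  expect_equal(min_hill_coefficient(0.75), 1.409, tolerance = 1e-3)
  expect_gte(min_hill_coefficient(0.98), 30)   # control-like ratio
  expect_error(min_hill_coefficient(0.5), "between 0.5 and 1")
  expect_error(min_hill_coefficient(1), "between 0.5 and 1")
  # validity of the solver flips at n_min (oracle: validity scan)
  for (rho in c(0.55, 0.7, 0.85, 0.95, 0.98)) {
    n_min <- min_hill_coefficient(rho)
    expect_false(solve_hill_threshold(rho, 1, n_min * 0.99)$valid)
    expect_true(solve_hill_threshold(rho, 1, n_min * 1.01)$valid)
  }
})

test_that("solve_mutant_hill recovers mutant parameters under shared beta/gamma", {
  control <- solve_hill_threshold(0.98, 1, n = 40)
  expect_true(control$valid)
  b <- control$beta_over_gamma
  # identity: mutant levels equal the control's own forward solves
  m1c <- oracle_ss_hill(b, 1, control$K, 40, 1)
  m2c <- oracle_ss_hill(b, 1, control$K, 40, 2)
  id <- solve_mutant_hill(control, m1c, m2c)
  expect_true(id$valid)
  expect_equal(id$n_mut, 40, tolerance = 1e-4)
  expect_equal(id$K_mut, control$K, tolerance = 1e-6)
  # synthetic mutant from known (K', n') with the control beta/gamma
  K_true <- 0.8; n_true <- 6
  m1 <- oracle_ss_hill(b, 1, K_true, n_true, 1)
  m2 <- oracle_ss_hill(b, 1, K_true, n_true, 2)
  rec <- solve_mutant_hill(control, m1, m2)
  expect_true(rec$valid)
  expect_equal(rec$K_mut, K_true, tolerance = 0.01 * K_true)
  expect_equal(rec$n_mut, n_true, tolerance = 0.01 * n_true)
  expect_lt(rec$max_residual, 1e-6)
  # a near-half ratio (0.52) is only reconcilable with a tiny, effectively
  # non-cooperative Hill coefficient: solvable, but excluded from any
  # "n > 2" statement
  near_half <- solve_mutant_hill(control, 0.71, 1.365)
  expect_true(near_half$valid)
  expect_lt(near_half$n_mut, 2)
  # a ratio below one half is inconsistent with any positive n
  bad <- solve_mutant_hill(control, 0.71, 1.5)
  expect_false(bad$valid)
  expect_match(bad$message, "no admissible solution")
})

test_that("solve_mutant_hill shared-K mode solves for n and beta/gamma", {
  control <- solve_hill_threshold(0.98, 1, n = 40)
  b_true <- 0.85; n_true <- 8
  m1 <- oracle_ss_hill(b_true, 1, control$K, n_true, 1)
  m2 <- oracle_ss_hill(b_true, 1, control$K, n_true, 2)
  rec <- solve_mutant_hill(control, m1, m2, assumption = "shared_K")
  expect_true(rec$valid)
  expect_equal(rec$n_mut, n_true, tolerance = 1e-4)
  expect_equal(rec$bg_mut, b_true, tolerance = 1e-6)
})

test_that("categorize reproduces the three-way assignment with config boundaries", {
  expect_identical(categorize(0.98), 1L)
  expect_identical(categorize(0.75), 2L)
  expect_identical(categorize(0.52), 3L)
  # boundary conventions: 0.9 -> 1, 0.6 -> 3 (both inclusive)
  expect_identical(categorize(0.9), 1L)
  expect_identical(categorize(0.6), 3L)
  # configurable thresholds
  expect_identical(categorize(0.75, thresholds = c(0.7, 0.5)), 1L)
  # clipping and domain errors
  expect_warning(cat1 <- categorize(1.05), "clipped")
  expect_identical(cat1, 1L)
  expect_error(categorize(0), "positive")
  expect_error(categorize(1.2), "not a plausible")
})

test_that("infer_step_params reads K and beta/gamma off the step geometry", {
  # category 1 (control): K = m2, beta/gamma only bounded below
  c1 <- infer_step_params(1, m1 = 1, m2 = 1)
  expect_equal(c1$K_est, 1)
  expect_false(c1$K_is_bound)
  expect_true(c1$bg_is_bound)
  # category 2: K = m2, beta/gamma = m1
  c2 <- infer_step_params(2, m1 = 0.73, m2 = 1)
  expect_equal(c2$K_est, 1)
  expect_equal(c2$bg_est, 0.73)
  expect_false(c2$bg_is_bound)
  # category 3: beta/gamma = m1, K bounded below by m2; m2 ~ 2*m1 consistent
  c3 <- infer_step_params(3, m1 = 0.71, m2 = 1.42)
  expect_equal(c3$bg_est, 0.71)
  expect_true(c3$K_is_bound)
  expect_equal(c3$K_est, 1.42)
  # category-3 inconsistency warning when m2 deviates from 2*m1
  expect_warning(infer_step_params(3, m1 = 0.71, m2 = 1.0), "inconsistency")
  # m1 marginally above m2 is clipped
  expect_warning(ccl <- infer_step_params(1, m1 = 1.02, m2 = 1), "clipping")
  expect_equal(ccl$K_est, 1)
})

test_that("no_feedback_steady_state gives c*beta/gamma and a ratio of one half", {
  expect_equal(no_feedback_steady_state(1, 1, 2)$m_ss, 2)
  expect_equal(no_feedback_steady_state(0, 1, 1)$m_ss, 0)
  withr::with_seed(16, {
    for (i in 1:20) {
      beta <- runif(1, 0.1, 5); gamma <- runif(1, 0.1, 5)
      expect_equal(no_feedback_steady_state(beta, gamma, 1)$m_ss /
                     no_feedback_steady_state(beta, gamma, 2)$m_ss, 0.5)
    }
  })
})

test_that("distance_effect_predict separates beta scaling from K scaling", {
  p <- model_params(1.2, 1, K = 1, n = Inf, c = 2)
  # pure distance effect (beta up): the repressed intersection stays at m = K
  d1 <- distance_effect_predict(p, beta_scale = 1.5, K_scale = 1)
  expect_equal(d1$ss2$m_ss, 1)
  # repression reduced (K up): the intersection moves
  d2 <- distance_effect_predict(p, beta_scale = 1, K_scale = 1.5)
  expect_equal(d2$ss2$m_ss, 1.5)   # 2*1.2 = 2.4 > 1.5, still repressed
  # deep-repression limit: huge beta pins both copies at K
  d3 <- distance_effect_predict(p, beta_scale = 100, K_scale = 1)
  expect_equal(d3$ratio, 1)
})

test_that("hill_vs_step_error is small at n = 4 and vanishes as n grows", {
  e4 <- hill_vs_step_error(rho = 0.75, m2 = 1, n_finite = 4)
  expect_true(e4$valid)
  expect_equal(e4$K_step, 1)
  expect_equal(e4$bg_step, 0.75)
  expect_true(is.finite(e4$rel_err_K) && is.finite(e4$rel_err_bg))
  e_big <- hill_vs_step_error(rho = 0.75, m2 = 1, n_finite = 2000)
  expect_lt(e_big$rel_err_K, 1e-3)
  expect_lt(e_big$rel_err_bg, 1e-3)
  expect_lt(e_big$rel_err_K, e4$rel_err_K)
  # inadmissible ratio at n = 4 propagates invalidity
  inv <- hill_vs_step_error(rho = 0.95, m2 = 1, n_finite = 4)
  expect_false(inv$valid)
  expect_true(is.na(inv$rel_err_K))
})

test_that("model objects round-trip through JSON with the inf sentinel", {
  p <- model_params(1.2, 0.9, K = Inf, n = Inf, c = 2)
  p2 <- params_from_json(params_to_json(p))
  expect_equal(unclass(p2), unclass(p))
  expect_match(as.character(params_to_json(p)), '"inf"')
  sol <- solve_hill_threshold(0.8, 1, 6)
  sol2 <- params_from_json(params_to_json(sol))
  expect_s3_class(sol2, "hill_solution")
  expect_equal(sol2$K, sol$K)
  cr <- infer_step_params(2, 0.73, 1)
  cr2 <- params_from_json(params_to_json(cr))
  expect_equal(cr2$bg_est, 0.73)
  expect_identical(cr2$category, 2L)
})
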