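# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: root finding via stats::uniroot, the bootstrap
# via exhaustive enumeration of the resample index space, ANOVA/Tukey via
# stats::aov + stats::TukeyHSD.

# steady state of c*beta/(1+(m/K)^n) = gamma*m by uniroot
oracle_ss_hill <- function(beta, gamma, K, n, c) {
  upper <- c * beta / gamma
  stats::uniroot(function(m) c * beta / (1 + (m / K)^n) - gamma * m,
                 interval = c(1e-15, upper + 1), tol = 1e-13)$root
}

# exhaustive shifted-mean bootstrap p-value: enumerates all n^n resample
# index tuples for each group (feasible for n <= 5)
oracle_shifted_boot_p <- function(control, mutant) {
  n_c <- length(control)
  n_m <- length(mutant)
  stopifnot(n_c <= 5, n_m <= 5)
  obs <- mean(control) - mean(mutant)
  mu <- mean(c(control, mutant))
  sc <- control - mean(control) + mu
  sm <- mutant - mean(mutant) + mu
  all_means <- function(x) {
    n <- length(x)
    idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    rowMeans(matrix(x[idx], nrow(idx)))
  }
  mc <- all_means(sc)
  mm <- all_means(sm)
  d <- outer(mc, mm, `-`)
  mean(abs(d) >= abs(obs) - 1e-12)
}

# Jaccard overlap between two index sets
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

make_step_scenario <- function(label, bg, K, noise_cv = 0.1, n = 50L) {
  genotype_scenario(label, bg = bg, K = K, noise_cv = noise_cv, n_embryos = n)
}

# random admissible (rho, n) pair for the inversion round trip
random_hill_params <- function() {
  list(beta = stats::runif(1, 0.5, 2), gamma = stats::runif(1, 0.5, 2),
       K = stats::runif(1, 0.2, 1.5), n = stats::runif(1, 2, 40))
}
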