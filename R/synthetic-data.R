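#' @title Synthetic-data generators
#' @description
#' Every input the analysis pipeline consumes — per-embryo fluorescence
#' intensity tables, striped embryo intensity images, binary hatching
#' outcomes and cross offspring counts — can be generated from known
#' ground-truth parameters, so parameter recovery is testable end to end
#' without any imaging data. All generators are pure functions of
#' (parameters, seed).
#' @name synthetic_data
NULL

#' Define a genotype scenario for simulation
#'
#' A scenario couples a step- or Hill-model parameter set (shared between
#' the 1- and 2-copy conditions) with an embryo-level noise model and a
#' viability probability. True per-condition means are the model steady
#' states; measured intensities scatter around them multiplicatively
#' (lognormal, coefficient of variation `noise_cv`).
#'
#' @param label Genotype name.
#' @param bg Net production per copy, \eqn{\beta/\gamma} (with `gamma`
#'   fixed at 1, `beta = bg`), in units of the control 2-copy mean.
#' @param K Repression threshold in the same units; `Inf` for no feedback.
#' @param n Hill coefficient; default `Inf` (step model).
#' @param noise_cv Embryo-level coefficient of variation (default 0.12,
#'   the visual scale of per-embryo scatter in this assay).
#' @param n_embryos Embryos per copy-number condition.
#' @param hatch_prob Bernoulli probability that an embryo hatches.
#' @param maternal Maternal genotype label (carried through, never modeled).
#' @return A `genotype_scenario` object.
#' @examples
#' sc <- genotype_scenario("control", bg = 1.2, K = 1)
#' head(simulate_measurements(sc, seed = 1))
#' @export
genotype_scenario <- function(label, bg, K, n = Inf, noise_cv = 0.12,
                              n_embryos = 50L, hatch_prob = 0.9,
                              maternal = "Df/CyO") {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            noise_cv >= 0, n_embryos >= 1,
            hatch_prob >= 0, hatch_prob <= 1)
  p2 <- model_params(beta = bg, gamma = 1, K = K, n = n, c = 2L)
  structure(
    list(label = label, params_2copy = p2, params_1copy = with_copies(p2, 1L),
         noise_cv = noise_cv, n_embryos = as.integer(n_embryos),
         hatch_prob = hatch_prob, maternal = maternal),
    class = "genotype_scenario"
  )
}

#' Built-in scenario presets
#'
#' Four step-model presets spanning the three dosage-ratio categories:
#' a compensating control (category 1), a feedback-null genotype with no
#' repression threshold (ratio 1/2), a partially compensating category-2
#' mutant and a category-3 mutant whose unrepressed level sits below its
#' threshold. The parameter values are simulation defaults chosen to
#' exercise each regime, not estimates for any real genotype.
#'
#' @param noise_cv,n_embryos Passed to every preset.
#' @return Named list of `genotype_scenario` objects.
#' @export
scenario_presets <- function(noise_cv = 0.12, n_embryos = 50L) {
  list(
    control = genotype_scenario("control", bg = 1.2, K = 1,
                                noise_cv = noise_cv, n_embryos = n_embryos,
                                hatch_prob = 0.92),
    no_feedback = genotype_scenario("no_feedback", bg = 0.71, K = Inf,
                                    noise_cv = noise_cv, n_embryos = n_embryos,
                                    hatch_prob = 0.10),
    category2_mutant = genotype_scenario("category2_mutant", bg = 0.73, K = 1,
                                         noise_cv = noise_cv,
                                         n_embryos = n_embryos,
                                         hatch_prob = 0.70),
    category3_mutant = genotype_scenario("category3_mutant", bg = 0.5, K = 1.5,
                                         noise_cv = noise_cv,
                                         n_embryos = n_embryos,
                                         hatch_prob = 0.55)
  )
}

scenario_true_means <- function(scenario) {
  c(m2 = steady_state_auto(scenario$params_2copy)$m_ss,
    m1 = steady_state_auto(scenario$params_1copy)$m_ss)
}

#' Simulate a per-embryo measurement table
#'
#' Draws `n_embryos` embryos for each copy-number condition of a scenario.
#' True condition means are the model steady states; per-embryo mean
#' intensities are lognormal around them with coefficient of variation
#' `noise_cv` (so `noise_cv = 0` reproduces the steady states exactly).
#' Expression-domain widths are drawn uniformly over the natural
#' population range (112-140 um, i.e. 16-20 nuclei at 7 um spacing).
#'
#' @param scenario A [genotype_scenario()].
#' @param seed Integer seed; the same seed always returns the identical
#'   table.
#' @return A data.frame with columns `embryo_id`, `genotype`,
#'   `maternal_genotype`, `copies`, `mean_intensity`, `width_um`, `stage`,
#'   and a `ground_truth` attribute recording the generating parameters
#'   and true means.
#' @export
simulate_measurements <- function(scenario, seed) {
  stopifnot(inherits(scenario, "genotype_scenario"))
  mu <- scenario_true_means(scenario)
  n <- scenario$n_embryos
  cv <- scenario$noise_cv
  withr::with_seed(as.integer(seed), {
    draw <- function(mean_level, copies, offset) {
      intens <- if (cv == 0) {
        rep(mean_level, n)
      } else {
        sdlog <- sqrt(log(1 + cv^2))
        # meanlog chosen so the arithmetic mean equals the model steady state
        stats::rlnorm(n, meanlog = log(mean_level) - sdlog^2 / 2, sdlog = sdlog)
      }
      data.frame(
        embryo_id = sprintf("%s_c%d_%03d", scenario$label, copies,
                            seq_len(n) + offset),
        genotype = scenario$label,
        maternal_genotype = scenario$maternal,
        copies = copies,
        mean_intensity = intens,
        width_um = stats::runif(n, 112, 140),
        stage = "nc14_mid_late",
        stringsAsFactors = FALSE
      )
    }
    out <- rbind(draw(mu[["m2"]], 2L, 0L), draw(mu[["m1"]], 1L, 0L))
  })
  attr(out, "ground_truth") <- list(
    label = scenario$label, m2_true = mu[["m2"]], m1_true = mu[["m1"]],
    rho_true = mu[["m1"]] / mu[["m2"]], noise_cv = cv,
    params_2copy = scenario$params_2copy, params_1copy = scenario$params_1copy
  )
  out
}

#' Simulate a striped embryo intensity image
#'
#' A rectangular intensity field emulating a ventral expression stripe:
#' rows run along the dorsoventral axis, columns along the
#' anterior-posterior axis. A band of the stated width, centered on the
#' ventral midline (middle rows), sits at `peak_intensity` over a uniform
#' `background`, plus additive Gaussian pixel noise. Ground truth (band
#' rows, width) is attached as attributes.
#'
#' @param length_um Anterior-posterior extent of the field (um).
#' @param dv_um Dorsoventral extent (um); must exceed `domain_width_um`.
#' @param domain_width_um True stripe width (um).
#' @param peak_intensity,background Intensity levels (arbitrary units).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param pixel_um Pixel size (um).
#' @param seed Integer seed.
#' @return A numeric matrix (rows = DV, cols = AP) with attributes
#'   `pixel_um`, `truth_rows` (row indices of the band) and
#'   `truth_width_um`.
#' @export
simulate_embryo_image <- function(length_um = 200, dv_um = 500,
                                  domain_width_um = 126,
                                  peak_intensity = 100, background = 10,
                                  noise_sd = 0, pixel_um = 2, seed = 1L) {
  stopifnot(domain_width_um < dv_um, pixel_um > 0, noise_sd >= 0)
  nr <- round(dv_um / pixel_um)
  nc <- round(length_um / pixel_um)
  half <- domain_width_um / pixel_um / 2
  center <- (nr + 1) / 2
  rows <- which(abs(seq_len(nr) - center) <= half)
  img <- matrix(background, nrow = nr, ncol = nc)
  img[rows, ] <- peak_intensity
  if (noise_sd > 0) {
    img <- img + withr::with_seed(as.integer(seed),
                                  matrix(stats::rnorm(nr * nc, 0, noise_sd),
                                         nr, nc))
  }
  attr(img, "pixel_um") <- pixel_um
  attr(img, "truth_rows") <- rows
  attr(img, "truth_width_um") <- length(rows) * pixel_um
  img
}

#' Simulate binary hatching outcomes
#'
#' Independent Bernoulli draws: 1 = hatched (viable), 0 = did not hatch.
#'
#' @param hatch_prob Probability of hatching, in \[0, 1\].
#' @param n Number of embryos.
#' @param seed Integer seed.
#' @return An integer vector of 0/1 of length `n`.
#' @export
simulate_viability <- function(hatch_prob, n, seed) {
  stopifnot(hatch_prob >= 0, hatch_prob <= 1, n >= 1)
  withr::with_seed(as.integer(seed),
                   as.integer(stats::rbinom(n, 1L, hatch_prob)))
}

#' Simulate offspring genotype counts from a cross
#'
#' Draws `n` surviving offspring from the class probabilities returned by
#' [expected_offspring()] — Mendelian fractions with lethal classes
#' removed and per-class survival factors applied. With a balancer
#' intercross and full homozygote survival the homozygote share is 1/3;
#' a survival factor `s` shifts the observed share to
#' \eqn{s/3 / (s/3 + 2/3)}.
#'
#' @param cross A [cross_spec()].
#' @param n Number of surviving offspring scored.
#' @param seed Integer seed.
#' @return A named integer vector of counts per surviving class.
#' @export
simulate_cross_offspring <- function(cross, n, seed) {
  probs <- expected_offspring(cross)
  counts <- withr::with_seed(as.integer(seed),
                             stats::rmultinom(1, n, probs)[, 1])
  stats::setNames(as.integer(counts), names(probs))
}
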