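#' @title Viability statistics
#' @description
#' Statistics for embryonic-viability assays: the shifted-mean bootstrap
#' test comparing hatch rates between a control and a mutant, Bonferroni
#' correction of the significance level across repeated comparisons,
#' percent-viable summaries, Mendelian expectations for balancer crosses
#' (accounting for lethal balancer homozygotes), and cuticle-phenotype
#' frequency tables.
#' @name viability_stats
NULL

#' Per-genotype binary viability dataset
#'
#' @param genotype Genotype label.
#' @param outcomes Binary vector: 1 = hatched (viable), 0 = not hatched.
#' @param replicate Optional replicate id per embryo (same length as
#'   `outcomes`); used only for the replicate-wise SD in
#'   [percent_viable()].
#' @return A `viability_dataset` object.
#' @export
viability_dataset <- function(genotype, outcomes, replicate = NULL) {
  stopifnot(is.character(genotype), length(genotype) == 1L,
            length(outcomes) >= 1L, all(outcomes %in% c(0, 1)))
  if (!is.null(replicate)) stopifnot(length(replicate) == length(outcomes))
  structure(list(genotype = genotype, outcomes = as.integer(outcomes),
                 replicate = replicate),
            class = "viability_dataset")
}

#' Percent viable with replicate-wise spread
#'
#' The mean of the binary outcomes equals the percent viable divided by
#' 100. When replicate ids are present, the SD across per-replicate
#' percentages is reported; otherwise `sd` is `NA`.
#'
#' @param dataset A [viability_dataset()].
#' @return A list: `percent`, `sd`, `n`.
#' @export
percent_viable <- function(dataset) {
  stopifnot(inherits(dataset, "viability_dataset"))
  pct <- 100 * mean(dataset$outcomes)
  sd_rep <- NA_real_
  if (!is.null(dataset$replicate) &&
      length(unique(dataset$replicate)) > 1L) {
    per_rep <- tapply(dataset$outcomes, dataset$replicate,
                      function(x) 100 * mean(x))
    sd_rep <- stats::sd(per_rep)
  }
  list(percent = pct, sd = sd_rep, n = length(dataset$outcomes))
}

#' Shifted-mean bootstrap test for a difference in hatch rates
#'
#' Two-sample bootstrap test of equal means. Replicates are pooled first;
#' both samples are then shifted to the combined mean (subtract each
#' sample's own mean, add the pooled mean), so the null hypothesis of
#' equal means holds exactly in the resampling population. Each bootstrap
#' iteration redraws both samples with replacement at their original
#' sizes; the p-value is the fraction of iterations whose absolute mean
#' difference reaches the observed absolute difference:
#' `p = #(|boot diff| >= |observed diff|) / n_boot` (tie convention
#' `">="`; set `tie = "gt"` for the strict-inequality variant).
#'
#' For binary (or any two-valued) samples the bootstrap mean is an exact
#' function of a binomial count, and the implementation uses that
#' reduction, making the paper-scale default of 1e7 iterations cheap; a
#' generic chunked resampling path covers arbitrary numeric input.
#'
#' @param control,mutant Numeric vectors (typically binary hatch
#'   outcomes), non-empty.
#' @param n_boot Number of bootstrap iterations (default 1e7).
#' @param seed Integer seed.
#' @param tie `">="` counts ties in the tail (default); `"gt"` does not.
#' @return A list of class `boot_test`: `p_value`, `obs_diff`, `n_boot`,
#'   `tie`, `n_control`, `n_mutant`.
#' @examples
#' shifted_mean_bootstrap(c(1, 1, 1, 0), c(1, 0, 0, 0),
#'                        n_boot = 1e4, seed = 1)
#' @export
shifted_mean_bootstrap <- function(control, mutant, n_boot = 1e7, seed = 1L,
                                   tie = c("geq", "gt")) {
  tie <- match.arg(tie)
  stopifnot(length(control) >= 1L, length(mutant) >= 1L, n_boot >= 1)
  n_c <- length(control)
  n_m <- length(mutant)
  obs <- mean(control) - mean(mutant)
  mu <- mean(c(control, mutant))
  shifted_c <- control - mean(control) + mu
  shifted_m <- mutant - mean(mutant) + mu

  out <- function(p) {
    structure(list(p_value = p, obs_diff = obs, n_boot = n_boot, tie = tie,
                   n_control = n_c, n_mutant = n_m),
              class = "boot_test")
  }
  # degenerate: both samples constant and equal -> every resample ties
  if (stats::sd(c(control, mutant)) == 0) return(out(1))

  # tail comparison with a guard against floating-point ties
  eps <- 1e-12 * max(1, abs(obs))
  in_tail <- function(diffs) {
    if (tie == "geq") abs(diffs) >= abs(obs) - eps else abs(diffs) > abs(obs) + eps
  }

  two_valued <- function(x) length(unique(x)) <= 2L
  count <- withr::with_seed(as.integer(seed), {
    if (two_valued(shifted_c) && two_valued(shifted_m)) {
      # exact binomial reduction: a resample mean of a two-valued sample is
      # determined by how many draws hit the upper value
      binom_means <- function(x, n_draws) {
        v <- sort(unique(x))
        if (length(v) == 1L) return(rep(v, n_boot))
        p_hi <- mean(x == v[2])
        s <- stats::rbinom(n_boot, n_draws, p_hi)
        (s * v[2] + (n_draws - s) * v[1]) / n_draws
      }
      diffs <- binom_means(shifted_c, n_c) - binom_means(shifted_m, n_m)
      sum(in_tail(diffs))
    } else {
      total <- 0
      chunk <- max(1L, min(n_boot, floor(2e6 / (n_c + n_m))))
      done <- 0
      while (done < n_boot) {
        b <- min(chunk, n_boot - done)
        mc <- colMeans(matrix(sample(shifted_c, n_c * b, replace = TRUE), n_c))
        mm <- colMeans(matrix(sample(shifted_m, n_m * b, replace = TRUE), n_m))
        total <- total + sum(in_tail(mc - mm))
        done <- done + b
      }
      total
    }
  })
  out(count / n_boot)
}

#' @export
print.boot_test <- function(x, ...) {
  cat(sprintf(
    "shifted-mean bootstrap: observed diff %.4g, p = %.4g (%g iterations, tie %s)\n",
    x$obs_diff, x$p_value, x$n_boot, x$tie))
  invisible(x)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Family-wise significance level, in (0, 1].
#' @param n_comparisons Number of comparisons (>= 1).
#' @return `alpha / n_comparisons` (e.g. 0.05/9 = 5.56e-3).
#' @export
bonferroni_alpha <- function(alpha, n_comparisons) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  stopifnot(is.numeric(n_comparisons), length(n_comparisons) == 1L,
            n_comparisons >= 1, n_comparisons == round(n_comparisons))
  alpha / n_comparisons
}

#' Specify a genetic cross
#'
#' Offspring classes with their raw Mendelian fractions, the classes that
#' are lethal (e.g. balancer homozygotes), and optional per-class survival
#' factors applied to the remaining classes.
#'
#' @param parents Length-2 character vector of parental genotypes.
#' @param classes Character vector of offspring genotype classes.
#' @param fractions Raw Mendelian fractions, same length as `classes`,
#'   summing to 1.
#' @param lethal Subset of `classes` that never survive.
#' @param survival Optional named numeric vector of survival factors in
#'   \[0, 1\] for (a subset of) the non-lethal classes; unnamed classes
#'   default to 1.
#' @return A `cross_spec` object.
#' @seealso [balancer_intercross()] for the standard mut/CyO x mut/CyO
#'   preset.
#' @export
cross_spec <- function(parents, classes, fractions, lethal = character(),
                       survival = NULL) {
  stopifnot(length(parents) == 2L, length(classes) == length(fractions),
            !anyDuplicated(classes), all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8, all(lethal %in% classes))
  if (!is.null(survival)) {
    stopifnot(!is.null(names(survival)), all(names(survival) %in% classes),
              all(survival >= 0), all(survival <= 1))
  }
  structure(list(parents = parents, classes = classes,
                 fractions = stats::setNames(fractions, classes),
                 lethal = lethal, survival = survival),
            class = "cross_spec")
}

#' Balancer intercross preset
#'
#' The standard `mut/CyO x mut/CyO` cross: offspring are 1/4 `mut/mut`,
#' 1/2 `mut/CyO` and 1/4 `CyO/CyO`; balancer homozygotes are lethal, so
#' the expected surviving homozygote share is 1/3 (33%). A survival factor
#' below 1 for the homozygote models semi-lethality.
#'
#' @param mut Label of the mutation-bearing chromosome.
#' @param balancer Balancer label (default "CyO").
#' @param homozygote_survival Survival factor for `mut/mut` (default 1).
#' @return A `cross_spec`.
#' @export
balancer_intercross <- function(mut = "mut", balancer = "CyO",
                                homozygote_survival = 1) {
  homo <- paste0(mut, "/", mut)
  het <- paste0(mut, "/", balancer)
  bal <- paste0(balancer, "/", balancer)
  surv <- if (homozygote_survival < 1) {
    stats::setNames(homozygote_survival, homo)
  } else {
    NULL
  }
  cross_spec(parents = c(het, het),
             classes = c(homo, het, bal),
             fractions = c(0.25, 0.5, 0.25),
             lethal = bal, survival = surv)
}

#' Expected surviving offspring fractions
#'
#' Removes lethal classes, applies survival factors and renormalizes so
#' the surviving-class fractions sum to 1.
#'
#' @param cross A [cross_spec()].
#' @return Named numeric vector of fractions over the surviving classes.
#' @examples
#' expected_offspring(balancer_intercross())  # homozygote share 1/3
#' @export
expected_offspring <- function(cross) {
  stopifnot(inherits(cross, "cross_spec"))
  keep <- setdiff(cross$classes, cross$lethal)
  if (length(keep) == 0L) stop("all offspring classes are lethal")
  fr <- cross$fractions[keep]
  if (!is.null(cross$survival)) {
    s <- cross$survival[keep]
    s[is.na(s)] <- 1
    fr <- fr * s
  }
  tot <- sum(fr)
  if (tot <= 0) stop("no offspring class survives")
  fr / tot
}

#' Cuticle phenotype frequency table
#'
#' @param counts Named non-negative integer vector of counts per severity
#'   class (e.g. normal / minor / major), with positive total.
#' @return A list: `proportions` (summing to 1), `counts`, `total`.
#' @export
phenotype_frequencies <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("phenotype counts sum to zero")
  list(proportions = counts / total, counts = counts, total = total)
}
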