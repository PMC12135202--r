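#' @title Dosage-compensation analysis
#' @description
#' Turns grouped per-embryo measurements into normalized 1-copy and 2-copy
#' levels and their ratio, tests whether the two dosages differ
#' (compensation), and feeds the step-function/Hill parameter inference.
#' All levels are normalized by the control 2-copy mean, so the control's
#' inferred threshold is 1 by construction.
#' @name dosage_analysis
NULL

#' Construct a dosage record from normalized levels
#'
#' Container for a genotype's normalized 2-copy level `m2`, 1-copy level
#' `m1` and their ratio `rho = m1/m2`. Use [estimate_dosage_record()] to
#' build one from raw per-embryo measurements; this constructor serves
#' printed or externally computed levels.
#'
#' @param genotype Genotype label.
#' @param m2,m1 Normalized mean levels (control 2-copy mean = 1).
#' @param n2,n1 Embryo counts behind each mean (optional).
#' @param ci Length-2 bootstrap interval for `rho` (optional).
#' @return A `dosage_record` object.
#' @export
dosage_record <- function(genotype, m2, m1, n2 = NA_integer_,
                          n1 = NA_integer_, ci = c(NA_real_, NA_real_)) {
  stopifnot(is.character(genotype), length(genotype) == 1L,
            m2 > 0, m1 > 0, length(ci) == 2L)
  structure(
    list(genotype = genotype, m2 = m2, m1 = m1, rho = m1 / m2,
         n2 = as.integer(n2), n1 = as.integer(n1),
         ci = as.numeric(ci)),
    class = "dosage_record"
  )
}

#' @export
print.dosage_record <- function(x, ...) {
  cat(sprintf("dosage_record %s: m2=%.4g m1=%.4g rho=%.4g", x$genotype,
              x$m2, x$m1, x$rho))
  if (all(is.finite(x$ci))) cat(sprintf(" [%.4g, %.4g]", x$ci[1], x$ci[2]))
  cat("\n")
  invisible(x)
}

#' Estimate a dosage record from per-embryo measurements
#'
#' Group means are normalized by the control 2-copy mean; the ratio is the
#' ratio of group means (not the mean of per-embryo ratios). A percentile
#' bootstrap over embryos (resampling the 1- and 2-copy groups
#' independently) gives the confidence interval for the ratio.
#'
#' @param two_copy,one_copy Numeric vectors of per-embryo mean intensities.
#' @param control_two_copy Control 2-copy measurements used as the
#'   normalizer (pass `two_copy` again for the control itself).
#' @param genotype Genotype label.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return A `dosage_record`.
#' @export
estimate_dosage_record <- function(two_copy, one_copy, control_two_copy,
                                   genotype = "genotype", n_boot = 2000L,
                                   seed = 1L, conf = 0.95) {
  if (length(two_copy) == 0L || length(one_copy) == 0L ||
      length(control_two_copy) == 0L) {
    stop("all measurement groups must be non-empty")
  }
  norm <- mean(control_two_copy)
  if (norm <= 0) stop("control 2-copy mean must be positive")
  m2 <- mean(two_copy) / norm
  m1 <- mean(one_copy) / norm
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      mean(sample(one_copy, replace = TRUE)) /
        mean(sample(two_copy, replace = TRUE))
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(a, 1 - a)))
  dosage_record(genotype, m2 = m2, m1 = m1,
                n2 = length(two_copy), n1 = length(one_copy), ci = ci)
}

#' Test dosage compensation between 1- and 2-copy conditions
#'
#' Delegates to [anova_tukey()] restricted to the two groups. The genotype
#' is called "compensated" when the 1- and 2-copy levels are not
#' significantly different at `alpha`, and "loss of compensation"
#' otherwise.
#'
#' @param two_copy,one_copy Numeric vectors of per-embryo intensities
#'   (each with at least two observations).
#' @param alpha Significance level (default 0.05).
#' @return A list: `decision` (character), `p_adj`, and the underlying
#'   `anova_tukey` object.
#' @export
compensation_test <- function(two_copy, one_copy, alpha = 0.05) {
  at <- anova_tukey(list(two_copy = two_copy, one_copy = one_copy),
                    alpha = alpha)
  p_adj <- at$table$p_adj[1]
  decision <- if (isTRUE(at$table$significant[1])) {
    "loss of compensation"
  } else {
    "compensated"
  }
  list(decision = decision, p_adj = p_adj, anova = at)
}

#' Analyze a panel of dosage records
#'
#' For each genotype: the three-way category from its ratio, the
#' step-function estimates (or one-sided bounds) of `K` and
#' \eqn{\beta/\gamma}, and the minimal admissible Hill coefficient for its
#' ratio (defined for ratios strictly between 0.5 and 1; `NA` otherwise).
#'
#' @param records List of `dosage_record` objects; the control must be
#'   among them.
#' @param control_label Genotype label of the control record (default:
#'   the first record).
#' @param thresholds Category boundaries passed to [categorize()].
#' @return A data.frame with one row per genotype and columns `genotype`,
#'   `m2`, `m1`, `rho`, `ci_low`, `ci_high`, `category`, `K_est`,
#'   `K_is_bound`, `bg_est`, `bg_is_bound`, `n_min`.
#' @export
genotype_panel_analysis <- function(records,
                                    control_label = records[[1]]$genotype,
                                    thresholds = c(0.9, 0.6)) {
  stopifnot(length(records) >= 1L,
            all(vapply(records, inherits, logical(1), "dosage_record")))
  labels <- vapply(records, `[[`, character(1), "genotype")
  if (!control_label %in% labels) {
    stop("control record '", control_label, "' not present in the panel")
  }
  do.call(rbind, lapply(records, function(r) {
    rho <- min(r$rho, 1)
    cat_i <- categorize(r$rho, thresholds)
    est <- infer_step_params(cat_i, m1 = min(r$m1, r$m2), m2 = r$m2)
    n_min <- if (rho > 0.5 && rho < 1) min_hill_coefficient(rho) else NA_real_
    data.frame(
      genotype = r$genotype, m2 = r$m2, m1 = r$m1, rho = r$rho,
      ci_low = r$ci[1], ci_high = r$ci[2], category = est$category,
      K_est = est$K_est, K_is_bound = est$K_is_bound,
      bg_est = est$bg_est, bg_is_bound = est$bg_is_bound,
      n_min = n_min, stringsAsFactors = FALSE
    )
  }))
}
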