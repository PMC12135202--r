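#' @title Pipeline orchestration
#' @description
#' Configuration handling and the end-to-end run: simulate per-embryo
#' measurements and viability outcomes for a set of genotype scenarios,
#' estimate normalized dosage records, run the category/step-function
#' inference, run the viability bootstrap against the control, and write
#' the panel CSV, viability CSV and a JSON report (plus optional
#' step-function plots).
#' @name pipeline_cli
NULL

#' Default run configuration
#'
#' All analysis defaults live in one block: category boundaries 0.9/0.6,
#' alpha 0.05, bootstrap iterations 1e7 (scale down for quick runs),
#' domain-detection threshold 0.5 with a 3-pixel box smoother. Scenarios
#' default to the four built-in presets.
#'
#' @param seed Base integer seed (mandatory for every stochastic stage;
#'   stage seeds are derived from it deterministically).
#' @param out_dir Output directory.
#' @param n_boot Bootstrap iterations for the viability test.
#' @param n_embryos Embryos per condition in simulated measurement tables.
#' @param n_viability Embryos per genotype in simulated viability assays.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1L, out_dir = "snadosage_out",
                               n_boot = 1e7, n_embryos = 50L,
                               n_viability = 200L) {
  presets <- scenario_presets(n_embryos = n_embryos)
  scenarios <- lapply(presets, function(sc) {
    list(label = sc$label, bg = sc$params_2copy$beta / sc$params_2copy$gamma,
         K = sc$params_2copy$K, n = sc$params_2copy$n,
         noise_cv = sc$noise_cv, n_embryos = sc$n_embryos,
         hatch_prob = sc$hatch_prob, n_viability = as.integer(n_viability))
  })
  structure(
    list(control = "control", scenarios = unname(scenarios),
         thresholds = list(category = c(0.9, 0.6), alpha = 0.05,
                           n_boot = n_boot, domain_threshold = 0.5,
                           smooth_px = 3L),
         seed = as.integer(seed), out_dir = out_dir, plots = FALSE),
    class = "run_config"
  )
}

#' Validate a run configuration
#'
#' Checks that every scenario label is defined exactly once, that the
#' control label is among them, that a seed is present, and that all
#' thresholds are in range. Errors before any computation.
#'
#' @param config A `run_config` list.
#' @return The validated config, invisibly.
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  labels <- vapply(config$scenarios, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("duplicate scenario label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (!config$control %in% labels) {
    stop("control label '", config$control, "' has no scenario definition")
  }
  if (is.null(config$seed) || !is.finite(config$seed)) {
    stop("a seed is mandatory for every stochastic stage")
  }
  th <- config$thresholds
  stopifnot(length(th$category) == 2L, th$category[1] > th$category[2],
            th$alpha > 0, th$alpha <= 1, th$n_boot >= 1,
            th$domain_threshold > 0, th$domain_threshold < 1)
  invisible(config)
}

scenario_from_config <- function(def) {
  genotype_scenario(def$label, bg = def$bg, K = def$K,
                    n = if (is.null(def$n)) Inf else def$n,
                    noise_cv = def$noise_cv, n_embryos = def$n_embryos,
                    hatch_prob = def$hatch_prob)
}

#' Read / write run configurations as JSON
#'
#' Infinite values (step-limit `n`, absent `K`) are stored as the string
#' `"inf"`. Parse -> serialize -> parse is the identity.
#'
#' @param path JSON file path.
#' @param config A `run_config` list.
#' @return `read_run_config` returns the validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyVector = TRUE)
  raw$scenarios <- lapply(raw$scenarios, function(sc) {
    sc$K <- inf_from_json(sc$K)
    sc$n <- if (is.null(sc$n)) Inf else inf_from_json(sc$n)
    sc
  })
  config <- structure(raw, class = "run_config")
  validate_run_config(config)
  config
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$scenarios <- lapply(out$scenarios, function(sc) {
    sc$K <- inf_to_json(sc$K)
    sc$n <- inf_to_json(sc$n)
    sc
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

run_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Stages, each seeded deterministically from `config$seed`:
#' \enumerate{
#'   \item simulate per-embryo measurement tables for every scenario;
#'   \item estimate normalized dosage records (bootstrap CIs) against the
#'     control 2-copy mean;
#'   \item categorize each genotype and infer step-function `K` and
#'     \eqn{\beta/\gamma} (panel CSV);
#'   \item simulate viability outcomes and test each mutant against the
#'     control with the shifted-mean bootstrap at the
#'     Bonferroni-corrected alpha (viability CSV);
#'   \item write a JSON report of all inferred parameters and the seeds
#'     used; optionally render per-genotype step-function plots.
#' }
#' Reruns with the same config and seed produce byte-identical outputs.
#'
#' @param config A `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @return Invisibly, a list with the panel and viability data.frames,
#'   the measurement table and all output paths.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  labels <- vapply(config$scenarios, `[[`, character(1), "label")

  run_log("simulate", "generating measurements for %d scenarios (seed %d)",
          length(labels), config$seed)
  scens <- lapply(config$scenarios, scenario_from_config)
  names(scens) <- labels
  meas <- lapply(seq_along(scens), function(i) {
    simulate_measurements(scens[[i]], seed = config$seed + i)
  })
  names(meas) <- labels
  meas_all <- do.call(rbind, meas)
  meas_path <- file.path(config$out_dir, "measurements.csv")
  utils::write.csv(meas_all, meas_path, row.names = FALSE)

  run_log("dosage", "estimating normalized dosage records (control: %s)",
          config$control)
  ctrl2 <- meas[[config$control]]
  ctrl2 <- ctrl2$mean_intensity[ctrl2$copies == 2L]
  records <- lapply(seq_along(meas), function(i) {
    tab <- meas[[i]]
    estimate_dosage_record(
      two_copy = tab$mean_intensity[tab$copies == 2L],
      one_copy = tab$mean_intensity[tab$copies == 1L],
      control_two_copy = ctrl2, genotype = labels[i],
      seed = config$seed + 1000L + i
    )
  })

  run_log("model", "categorization and step-function inference")
  panel <- genotype_panel_analysis(records, control_label = config$control,
                                   thresholds = th$category)
  panel_path <- file.path(config$out_dir, "panel.csv")
  utils::write.csv(panel, panel_path, row.names = FALSE)

  run_log("viability", "bootstrap tests at n_boot = %g", th$n_boot)
  outcomes <- lapply(seq_along(scens), function(i) {
    simulate_viability(scens[[i]]$hatch_prob, config$scenarios[[i]]$n_viability,
                       seed = config$seed + 2000L + i)
  })
  names(outcomes) <- labels
  mutants <- setdiff(labels, config$control)
  alpha_corr <- bonferroni_alpha(th$alpha, max(1L, length(mutants)))
  viab <- do.call(rbind, lapply(seq_along(labels), function(i) {
    lab <- labels[i]
    p_boot <- if (lab == config$control) NA_real_ else {
      shifted_mean_bootstrap(outcomes[[config$control]], outcomes[[lab]],
                             n_boot = th$n_boot,
                             seed = config$seed + 3000L + i)$p_value
    }
    data.frame(genotype = lab, n = length(outcomes[[lab]]),
               percent_viable = 100 * mean(outcomes[[lab]]),
               p_boot = p_boot, alpha_corrected = alpha_corr,
               significant = !is.na(p_boot) & p_boot < alpha_corr,
               stringsAsFactors = FALSE)
  }))
  viab_path <- file.path(config$out_dir, "viability.csv")
  utils::write.csv(viab, viab_path, row.names = FALSE)

  plot_paths <- character(0)
  if (isTRUE(config$plots)) {
    run_log("plots", "rendering step-function plots")
    plot_paths <- vapply(seq_len(nrow(panel)), function(i) {
      row <- panel[i, ]
      cr <- new_category_result(row$category, row$K_est, row$bg_est,
                                row$K_is_bound, row$bg_is_bound)
      dr <- dosage_record(row$genotype, m2 = row$m2, m1 = row$m1)
      f <- file.path(config$out_dir, paste0("step_", row$genotype, ".png"))
      render_step_plot(cr, dr, file = f)
      f
    }, character(1))
  }

  report <- list(
    config = unclass(config),
    seeds = list(base = config$seed,
                 measurements = config$seed + seq_along(labels),
                 dosage_bootstrap = config$seed + 1000L + seq_along(labels),
                 viability_sim = config$seed + 2000L + seq_along(labels),
                 viability_bootstrap = config$seed + 3000L + seq_along(labels)),
    panel = panel, viability = viab
  )
  report$config$scenarios <- lapply(report$config$scenarios, function(sc) {
    sc$K <- inf_to_json(sc$K)
    sc$n <- inf_to_json(sc$n)
    sc
  })
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  run_log("done", "outputs in %s", config$out_dir)

  invisible(list(panel = panel, viability = viab, measurements = meas_all,
                 paths = c(measurements = meas_path, panel = panel_path,
                           viability = viab_path, report = report_path,
                           plots = plot_paths)))
}

#' Render the step-function steady-state plot for a genotype
#'
#' Production step(s) for 1 and 2 copies (solid and dotted), the
#' degradation identity line f(m) = m, and the steady-state intersections
#' (solid marker for 2 copies, open for 1 copy). Parameters known only as
#' one-sided bounds are drawn as arrows rather than points.
#'
#' @param category_result A `category_result` from [infer_step_params()].
#' @param dosage_record The matching `dosage_record` (for the measured
#'   steady-state levels).
#' @param file Optional PNG path; when `NULL`, draws on the active device.
#' @return The file path (or `NULL`), invisibly.
#' @export
render_step_plot <- function(category_result, dosage_record, file = NULL) {
  stopifnot(inherits(category_result, "category_result"),
            inherits(dosage_record, "dosage_record"))
  cr <- category_result
  dr <- dosage_record
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 480)
    on.exit(grDevices::dev.off())
  }
  K <- cr$K_est
  bg <- cr$bg_est
  xmax <- max(2 * bg, K, dr$m2) * 1.3
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, xmax),
                 xlab = "m (normalized)", ylab = "f(m)",
                 main = sprintf("%s (category %d)", dr$genotype, cr$category))
  graphics::abline(0, 1, col = "blue", lwd = 2)
  step_xy <- function(level) {
    graphics::segments(0, level, K, level, col = "red", lwd = 2,
                       lty = if (level == bg) 3 else 1)
    graphics::segments(K, 0, K, level, col = "red", lwd = 2,
                       lty = if (level == bg) 3 else 1)
  }
  step_xy(2 * bg)
  step_xy(bg)
  graphics::points(dr$m2, dr$m2, pch = 19, col = "purple", cex = 1.6)
  graphics::points(dr$m1, dr$m1, pch = 1, col = "purple", cex = 1.6)
  if (cr$bg_is_bound) {
    graphics::arrows(K, 2 * bg, K, 2 * bg + 0.15 * xmax, col = "red",
                     length = 0.1)
  }
  if (cr$K_is_bound) {
    graphics::arrows(K, 0.05 * xmax, K + 0.15 * xmax, 0.05 * xmax,
                     col = "red", length = 0.1)
  }
  graphics::legend("topright", bty = "n",
                   legend = c("production (2 copies)", "production (1 copy)",
                              "degradation", "s.s. 2 copies", "s.s. 1 copy"),
                   col = c("red", "red", "blue", "purple", "purple"),
                   lty = c(1, 3, 1, NA, NA), pch = c(NA, NA, NA, 19, 1))
  invisible(file)
}
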