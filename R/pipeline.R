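#' Default pipeline configuration
#'
#' Nested configuration driving [run_pipeline()]: data source (the packaged
#' measured table, a synthetic run table, or a user CSV), design and
#' reduction settings, the optimisation request, the Tukey groupings and the
#' optional mixing simulation. Any subset can be overridden via a YAML file
#' ([read_pipeline_config()]) or a nested list.
#'
#' @return Nested list of defaults.
#' @export
pdm_default_config <- function() {
  list(
    seed = 1L,
    data = list(
      source = "fixture",    # "fixture", "synthetic" or "csv"
      path = NULL,           # for source = "csv"
      sd_size = 6, sd_pdi = 0.02, zeta_mean = -31.5, zeta_sd = 4
    ),
    model = list(
      alpha = 0.1,
      responses = c("z_average_nm", "pdi", "zeta_mv")
    ),
    optimize = list(
      response = "z_average_nm", sense = "min",
      frr_bounds = c(1, 12), tfr_bounds = c(3, 18)
    ),
    tukey = list(responses = c("pdi", "zeta_mv"), alpha = 0.05),
    mixing = list(
      enabled = FALSE, frr = c(1, 3, 5, 9), tfr = 18,
      ny = 30, stations = NULL, dispersion_factor = 1, threshold = 90
    )
  )
}

#' Read a pipeline configuration file
#'
#' YAML with the structure of [pdm_default_config()]; missing entries take
#' their defaults.
#'
#' @param path YAML file path.
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_invalid("no such config file: ", path)
  user <- yaml::read_yaml(path)
  modifyList(pdm_default_config(), user)
}

fmt_num <- function(x, digits = 6) formatC(x, digits = digits, format = "g")

#' Run the full analysis pipeline
#'
#' Orchestrates the stages of the study in order: obtain a run table (measured
#' fixture, synthetic generation on the 29-run design, or a user CSV), fit
#' and reduce the quadratic models for each response, compute goodness-of-fit
#' reports, optimise the requested response over the experimental region,
#' group conditions by Tukey-Kramer letters, and optionally run the mixing
#' simulator. All artefacts are written to `output_dir` as delimited text plus
#' a structured log; results are deterministic given the configured seed.
#'
#' @param config nested list as from [pdm_default_config()] or
#'   [read_pipeline_config()].
#' @param output_dir directory for the report bundle (created if needed);
#'   `NULL` writes nothing.
#' @param quiet suppress progress messages.
#' @return A list of class `pdm_report` with elements `runs`, `models`
#'   (reduced models + ANOVA per response), `optimum`, `tukey` and `mixing`.
#' @export
run_pipeline <- function(config = pdm_default_config(), output_dir = NULL,
                         quiet = FALSE) {
  cfg <- modifyList(pdm_default_config(), config)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  runs <- stage("data", switch(cfg$data$source,
    fixture = pdm_runs(),
    csv = load_run_table(cfg$data$path),
    synthetic = {
      design <- build_cccr_design(pdm_design_spec(seed = cfg$seed))
      generate_run_table(
        design,
        truth_spec(sd_size = cfg$data$sd_size, sd_pdi = cfg$data$sd_pdi,
                   zeta_mean = cfg$data$zeta_mean, zeta_sd = cfg$data$zeta_sd),
        seed = cfg$seed + 1L
      )
    },
    stop_invalid("unknown data source '", cfg$data$source, "'")
  ))
  say("stage=data source=%s runs=%d seed=%d factor_sum=%s",
      cfg$data$source, nrow(runs), cfg$seed,
      fmt_num(sum(runs$frr) + sum(runs$tfr)))

  models <- lapply(cfg$model$responses, function(resp) {
    red <- stage(paste0("model_", resp),
                 reduce_model(runs, resp, alpha = cfg$model$alpha))
    say("stage=model response=%s terms={%s} r2=%s significant=%s",
        resp, paste(red$model$terms, collapse = ","),
        fmt_num(red$anova$r_squared), red$significant)
    red
  })
  names(models) <- cfg$model$responses

  optimum <- NULL
  opt_resp <- cfg$optimize$response
  if (!is.null(opt_resp) && opt_resp %in% names(models) &&
      models[[opt_resp]]$significant) {
    optimum <- stage("optimize", optimize_response(
      models[[opt_resp]]$model,
      bounds = list(frr = cfg$optimize$frr_bounds, tfr = cfg$optimize$tfr_bounds),
      sense = cfg$optimize$sense
    ))
    say("stage=optimize response=%s frr=%s tfr=%s predicted=%s",
        opt_resp, fmt_num(optimum$frr), fmt_num(optimum$tfr),
        fmt_num(optimum$predicted))
  }

  tukey <- lapply(cfg$tukey$responses, function(resp) {
    tg <- stage(paste0("tukey_", resp),
                tukey_groups(runs, resp, alpha = cfg$tukey$alpha))
    say("stage=tukey response=%s classes=%d", resp, attr(tg, "n_classes"))
    tg
  })
  names(tukey) <- cfg$tukey$responses

  mixing <- NULL
  if (isTRUE(cfg$mixing$enabled)) {
    mixing <- stage("mixing", mixing_study(
      frr_values = cfg$mixing$frr, tfr = cfg$mixing$tfr,
      properties = property_model(dispersion_factor = cfg$mixing$dispersion_factor),
      ny = cfg$mixing$ny, stations = cfg$mixing$stations,
      threshold = cfg$mixing$threshold
    ))
    say("stage=mixing frr={%s} tfr=%s", paste(cfg$mixing$frr, collapse = ","),
        fmt_num(cfg$mixing$tfr))
  }

  report <- structure(
    list(config = cfg, runs = runs, models = models, optimum = optimum,
         tukey = tukey, mixing = mixing, log = log_lines),
    class = "pdm_report"
  )
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

write_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  save_run_table(report$runs, file.path(output_dir, "runs.csv"))

  summary_rows <- lapply(names(report$models), function(resp) {
    red <- report$models[[resp]]
    a <- red$anova
    data.frame(
      response = resp,
      terms = paste(red$model$terms, collapse = " "),
      r2_percent = round(100 * a$r_squared, 2),
      r2_adj_percent = round(100 * a$r_squared_adj, 2),
      r2_pred_percent = round(100 * a$r_squared_pred, 2),
      f_value = round(a$model_f, 2),
      p_value = signif(a$model_p, 3),
      significant = red$significant
    )
  })
  write.csv(do.call(rbind, summary_rows),
            file.path(output_dir, "model_summary.csv"), row.names = FALSE)

  for (resp in names(report$models)) {
    tt <- report$models[[resp]]$anova$term_table
    tt$estimate <- signif(tt$estimate, 6)
    tt$se <- signif(tt$se, 6)
    tt$f <- signif(tt$f, 6)
    tt$p <- signif(tt$p, 6)
    write.csv(tt, file.path(output_dir, paste0("anova_", resp, ".csv")),
              row.names = FALSE)
  }

  if (!is.null(report$optimum)) {
    o <- report$optimum
    writeLines(c(
      sprintf("response: %s", report$config$optimize$response),
      sprintf("sense: %s", o$sense),
      sprintf("frr: %s", fmt_num(o$frr)),
      sprintf("tfr: %s", fmt_num(o$tfr)),
      sprintf("predicted: %s", fmt_num(o$predicted)),
      sprintf("se_fit: %s", fmt_num(o$se_fit)),
      sprintf("ci95: [%s, %s]", fmt_num(o$ci[1]), fmt_num(o$ci[2])),
      sprintf("at_bound: frr=%s tfr=%s", o$at_bound["frr"], o$at_bound["tfr"])
    ), file.path(output_dir, "optimum.txt"))
  }

  for (resp in names(report$tukey)) {
    write.csv(as.data.frame(report$tukey[[resp]]),
              file.path(output_dir, paste0("tukey_", resp, ".csv")),
              row.names = FALSE)
  }

  if (!is.null(report$mixing)) {
    write.csv(as.data.frame(report$mixing),
              file.path(output_dir, "mixing_distances.csv"), row.names = FALSE)
    profs <- attr(report$mixing, "profiles")
    prof_df <- do.call(rbind, lapply(names(profs), function(f) {
      cbind(frr = as.numeric(f), as.data.frame(profs[[f]]))
    }))
    write.csv(prof_df, file.path(output_dir, "mixing_profiles.csv"),
              row.names = FALSE)
  }

  writeLines(report$log, file.path(output_dir, "pipeline.log"))
  invisible(output_dir)
}

#' @export
print.pdm_report <- function(x, ...) {
  cat("Pipeline report\n===============\n")
  cat(sprintf("Runs: %d (%s)\n", nrow(x$runs), x$config$data$source))
  for (resp in names(x$models)) {
    red <- x$models[[resp]]
    cat(sprintf("- %s: terms {%s}, R2 = %.2f%%%s\n", resp,
                paste(red$model$terms, collapse = ", "),
                100 * red$anova$r_squared,
                if (red$significant) "" else " (not significant)"))
  }
  if (!is.null(x$optimum)) print(x$optimum)
  for (resp in names(x$tukey)) {
    cat(sprintf("- Tukey %s: %d letter class(es)\n", resp,
                attr(x$tukey[[resp]], "n_classes")))
  }
  if (!is.null(x$mixing)) {
    cat("- mixing distances (mm):",
        paste(sprintf("FRR %.0f: %.1f", x$mixing$frr, x$mixing$distance_mm),
              collapse = ", "), "\n")
  }
  invisible(x)
}
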