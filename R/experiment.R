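# Full-experiment orchestration: simulate -> kinships -> fit model variants
# across heritability scenarios -> evaluate (+ optional cross-validation),
# from a single config, with per-stage derived seeds and on-disk artifacts.

H2_SCENARIOS <- c("0.3", "0.5", "0.7", "mixed", "historical")

#' Build or validate an experiment configuration
#'
#' @param simulate Named list of arguments for [simulate_hybrid_study()]
#'   (e.g. `n_lines`, `n_loci`, `n_per_group`, `n_traits`, `divergence`).
#' @param scenarios Character vector of heritability scenarios: fixed
#'   `"0.3"`, `"0.5"`, `"0.7"`, `"mixed"` (0.3/0.5/0.7/0.7/0.3) or
#'   `"historical"` (0.569/0.662/0.381/0.57/0.418), or a list of numeric
#'   per-trait vectors.
#' @param models Subset of `c("UV-A", "UV-AD", "MV-A", "MV-AD")`.
#' @param reml List with `tol` and `max_iter`.
#' @param cv List with `enabled`, `k`; set `enabled = FALSE` to skip
#'   cross-validation.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param output_dir Where [run_experiment()] writes artifacts.
#' @return Validated list of class `"experiment_config"`.
#' @export
experiment_config <- function(simulate = list(), scenarios = "historical",
                              models = MODEL_VARIANTS,
                              reml = list(tol = 1e-6, max_iter = 500L),
                              cv = list(enabled = TRUE, k = 10L),
                              seed = 1L, output_dir = "gblupad_results") {
  if (length(models) == 0L) {
    abort("At least one model is required.", class = "gblupad_config_error")
  }
  models <- match.arg(models, MODEL_VARIANTS, several.ok = TRUE)
  if (length(scenarios) == 0L) {
    abort("At least one scenario is required.", class = "gblupad_config_error")
  }
  if (is.character(scenarios)) {
    bad <- setdiff(scenarios, H2_SCENARIOS)
    if (length(bad) > 0L) {
      abort(sprintf("Unknown scenario(s): %s", paste(bad, collapse = ", ")),
            class = "gblupad_config_error")
    }
    scenarios <- as.list(scenarios)
  }
  n_loci <- simulate$n_loci %||% formals(simulate_hybrid_study)$n_loci
  n_qtn <- (simulate$n_add_qtn %||% 100L) + (simulate$n_dom_qtn %||% 100L)
  if (n_qtn > n_loci) {
    abort("`n_loci` is smaller than the requested QTN architecture.",
          class = "gblupad_config_error")
  }
  reml$tol <- reml$tol %||% 1e-6
  reml$max_iter <- reml$max_iter %||% 500L
  cv$enabled <- cv$enabled %||% TRUE
  cv$k <- cv$k %||% 10L
  structure(
    list(simulate = simulate, scenarios = scenarios, models = models,
         reml = reml, cv = cv, seed = seed, output_dir = output_dir),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from a YAML file
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [experiment_config()].
#' @return An `"experiment_config"`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw[intersect(
    names(raw),
    names(formals(experiment_config))
  )])
}

scenario_h2 <- function(scenario, n_traits) {
  if (is.numeric(scenario)) {
    return(rep_len(scenario, n_traits))
  }
  switch(scenario,
    "0.3" = rep(0.3, n_traits),
    "0.5" = rep(0.5, n_traits),
    "0.7" = rep(0.7, n_traits),
    "mixed" = resolve_h2("mixed", seq_len(n_traits)),
    "historical" = resolve_h2("historical", seq_len(n_traits)),
    abort(sprintf("Unknown scenario: %s", scenario))
  )
}

scenario_label <- function(scenario) {
  if (is.numeric(scenario)) {
    paste0("h2_", paste(scenario, collapse = "-"))
  } else {
    scenario
  }
}

#' Run the full model-comparison experiment
#'
#' For each heritability scenario: simulate a hybrid study, build the
#' additive and dominance relationship matrices, fit the requested model
#' variants, evaluate them against the simulation truth, and (optionally)
#' run k-fold cross-validation. Artifacts (genotypes, phenotypes, truth,
#' relationship matrices, per-fit variance-component reports, evaluation
#' and CV tables, and a master log with all seeds) are written under
#' `config$output_dir`; every file is regenerated identically from the
#' config and master seed.
#'
#' @param config An `"experiment_config"` (or arguments for one).
#' @param quiet Suppress progress messages.
#' @return A tibble: one row per scenario x model x trait x statistic,
#'   with CV summaries appended (`statistic = "cv_corr"`).
#' @export
run_experiment <- function(config = experiment_config(), quiet = FALSE) {
  if (!inherits(config, "experiment_config")) {
    config <- do.call(experiment_config, config)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  log_lines <- c(
    sprintf("gblupad %s", as.character(utils::packageVersion("gblupad"))),
    sprintf("R %s", getRversion()),
    sprintf("master seed: %s", config$seed),
    sprintf("models: %s", paste(config$models, collapse = ", "))
  )
  results <- list()

  for (si in seq_along(config$scenarios)) {
    scen <- config$scenarios[[si]]
    label <- scenario_label(scen)
    scen_dir <- file.path(config$output_dir, label)
    dir.create(scen_dir, showWarnings = FALSE)
    scen_seed <- derive_seed(config$seed, 100L + si)
    say("scenario %s (seed %d)", label, scen_seed)

    sim_args <- config$simulate
    n_traits <- sim_args$n_traits %||% 5L
    sim_args$h2 <- scenario_h2(scen, n_traits)
    sim_args$seed <- scen_seed
    study <- tryCatch(
      do.call(simulate_hybrid_study, sim_args),
      error = function(e) abort(sprintf("[simulate:%s] %s", label, conditionMessage(e)))
    )
    write_genotypes(study$hybrids, file.path(scen_dir, "hybrid_genotypes.csv"))
    utils::write.csv(study$pheno, file.path(scen_dir, "phenotypes.csv"),
                     row.names = FALSE)
    truth_df <- data.frame(
      hybrid = rownames(study$truth$g),
      study$truth$g,
      check.names = FALSE
    )
    utils::write.csv(truth_df, file.path(scen_dir, "true_genetic_values.csv"),
                     row.names = FALSE)
    utils::write.csv(study$truth$parametric,
                     file.path(scen_dir, "parametric_variances.csv"),
                     row.names = FALSE)
    write_grm(study$A, file.path(scen_dir, "A.csv"))
    write_grm(study$D, file.path(scen_dir, "D.csv"))
    jsonlite::write_json(
      list(
        qtn_additive = study$arch$qtn_additive,
        qtn_dominance = study$arch$qtn_dominance,
        pleiotropy_table = study$arch$pleiotropy_table,
        h2 = as.list(stats::setNames(sim_args$h2, study$arch$traits))
      ),
      file.path(scen_dir, "architecture.json")
    )
    log_lines <- c(log_lines, sprintf("scenario %s: seed %d", label, scen_seed))

    for (mod in config$models) {
      say("  fitting %s", mod)
      fit <- tryCatch(
        fit_gblup(study$pheno, study$A, study$D, variant = mod,
                  tol = config$reml$tol, max_iter = config$reml$max_iter),
        error = function(e) abort(sprintf("[fit:%s:%s] %s", label, mod, conditionMessage(e)))
      )
      jsonlite::write_json(
        list(
          variant = mod,
          converged = fit$converged, n_iter = fit$n_iter,
          loglik = fit$loglik,
          V_alpha = fit$vc$V_alpha, V_delta = fit$vc$V_delta,
          V_e = fit$vc$V_e, beta = as.list(fit$beta)
        ),
        file.path(scen_dir, sprintf("fit_%s.json", mod)),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      utils::write.csv(
        tidy.gblup_fit(fit, "blup"),
        file.path(scen_dir, sprintf("blup_%s.csv", mod)),
        row.names = FALSE
      )
      ev <- evaluate_fit(fit, study$truth, study$pheno)
      ev$scenario <- label
      ev$model <- mod
      results[[length(results) + 1L]] <- ev

      if (isTRUE(config$cv$enabled)) {
        say("  %d-fold CV for %s", config$cv$k, mod)
        cv <- tryCatch(
          kfold_cv(study$pheno, study$A, study$D, variant = mod,
                   k = config$cv$k, seed = derive_seed(scen_seed, 7L),
                   tol = config$reml$tol, max_iter = config$reml$max_iter),
          error = function(e) abort(sprintf("[cv:%s:%s] %s", label, mod, conditionMessage(e)))
        )
        cv_tbl <- tibble::tibble(
          trait = cv$summary$trait,
          statistic = "cv_corr",
          component = "total",
          value = cv$summary$mean_corr,
          sd = cv$summary$sd_corr,
          scenario = label, model = mod
        )
        results[[length(results) + 1L]] <- cv_tbl
      }
    }
    ev_all <- dplyr::bind_rows(results)
    utils::write.csv(
      ev_all[ev_all$scenario == label, ],
      file.path(scen_dir, "evaluation.csv"),
      row.names = FALSE
    )
  }
  out <- dplyr::bind_rows(results)
  utils::write.csv(out, file.path(config$output_dir, "evaluation_all.csv"),
                   row.names = FALSE)
  writeLines(log_lines, file.path(config$output_dir, "experiment_log.txt"))
  out
}

#' Comparison plot of evaluation statistics across models
#'
#' A faceted summary in the spirit of per-trait bar charts comparing the
#' model variants on a chosen statistic.
#'
#' @param results Tibble returned by [run_experiment()].
#' @param statistic One of the `statistic` values in `results` (e.g.
#'   `"r_gg"`, `"cv_corr"`, `"h2_hat"`).
#' @param component Component to display (default `"total"`).
#' @return A ggplot object.
#' @export
plot_model_comparison <- function(results, statistic = "r_gg",
                                  component = "total") {
  dat <- results[results$statistic == statistic &
                   results$component == component, , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$trait, y = .data$value,
                                    fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = NULL, y = statistic, fill = NULL) +
    ggplot2::theme_minimal()
}
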