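# Model-comparison statistics and k-fold cross-validation.

#' Pearson correlation between parametric and estimated genetic values
#'
#' @param g_true,g_hat Numeric vectors of equal length (>= 3) with nonzero
#'   variance.
#' @return Pearson correlation coefficient.
#' @export
predictive_correlation <- function(g_true, g_hat) {
  if (length(g_true) != length(g_hat)) {
    abort("`g_true` and `g_hat` must have equal length.")
  }
  if (length(g_true) < 3L) {
    abort("Need at least three pairs.")
  }
  if (sd(g_true) == 0 || sd(g_hat) == 0) {
    abort("Zero variance in the genetic values.")
  }
  cor(g_true, g_hat)
}

#' Estimated heritability coefficient
#'
#' Ratio of the sample covariance between estimated genetic values and
#' phenotypes to the phenotypic variance:
#' \deqn{\hat h^2 = cov(\hat g, y) / var(y)}
#' For additive models \eqn{\hat g = \hat\alpha}; for additive-dominance
#' models \eqn{\hat g = \hat\alpha + \hat\delta}.
#'
#' @param g_hat Estimated genetic values.
#' @param y Phenotypes (same length, nonzero variance).
#' @return The heritability coefficient.
#' @export
estimated_heritability <- function(g_hat, y) {
  if (length(g_hat) != length(y)) {
    abort("`g_hat` and `y` must have equal length.")
  }
  if (var(y) == 0) {
    abort("`y` has zero variance.")
  }
  cov(g_hat, y) / var(y)
}

#' Predicted residual error sum of squares (PRESS)
#'
#' \deqn{PRESS = \sum_i (\hat\theta_i - \theta_i)^2}
#' applied to genetic-effect vectors (additive, dominance, total) or to
#' variance-component estimates against their parametric values.
#'
#' @param theta_hat,theta Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
press <- function(theta_hat, theta) {
  if (length(theta_hat) != length(theta)) {
    abort("`theta_hat` and `theta` must have equal length.")
  }
  sum((theta_hat - theta)^2)
}

#' Evaluate a GBLUP fit against simulation truth
#'
#' Computes, per trait, the three model-comparison statistics: the Pearson
#' correlation between parametric and estimated genetic values (total,
#' additive and — for AD variants — dominance components), the PRESS of
#' the same components, the PRESS of the variance-component estimates
#' against the parametric locus-sum values, and the estimated heritability
#' coefficient `cov(g_hat, y) / var(y)`.
#'
#' @param fit A `"gblup_fit"`.
#' @param truth A `"hybrid_truth"` (from [simulate_phenotypes()] or
#'   [simulate_hybrid_study()]).
#' @param data The phenotype table the model was fitted to (needed for the
#'   heritability coefficient); id column as in [fit_gblup()].
#' @param id_col Name or index of the id column.
#' @return A tibble of class `"gblup_eval"` with columns `trait`,
#'   `statistic` (`r_gg`, `press`, `h2_hat`), `component` (`total`,
#'   `additive`, `dominance`, `vc_alpha`, `vc_delta`) and `value`.
#' @export
evaluate_fit <- function(fit, truth, data, id_col = 1L) {
  ids <- rownames(truth$g)
  stopifnot(all(ids %in% fit$ids))
  data <- as.data.frame(data)
  dat_ids <- as.character(data[[id_col]])
  traits <- fit$traits
  dominance <- !is.null(fit$vc$V_delta)
  pv <- truth$parametric

  rows <- list()
  for (tr in traits) {
    k <- match(tr, truth$traits)
    g_true <- truth$g[, k] - truth$mu[[k]]
    ga_true <- truth$g_alpha[ids, k]
    gd_true <- truth$g_delta[ids, k]
    a_hat <- fit$alpha_hat[ids, tr]
    d_hat <- fit$delta_hat[ids, tr]
    g_hat <- a_hat + d_hat
    y <- data[[tr]][match(ids, dat_ids)]
    keep <- !is.na(y)

    add_row <- function(statistic, component, value) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        trait = tr, statistic = statistic, component = component,
        value = value
      )
    }
    add_row("r_gg", "total", predictive_correlation(g_true, g_hat))
    add_row("r_gg", "additive", predictive_correlation(ga_true, a_hat))
    add_row("press", "total", press(g_hat, g_true))
    add_row("press", "additive", press(a_hat, ga_true))
    if (dominance) {
      if (sd(gd_true) > 0 && sd(d_hat) > 0) {
        add_row("r_gg", "dominance", predictive_correlation(gd_true, d_hat))
      }
      add_row("press", "dominance", press(d_hat, gd_true))
    }
    # variance-component recovery (locus-sum parametric reference)
    s2a_hat <- fit$vc$V_alpha[tr, tr]
    add_row("press", "vc_alpha", press(s2a_hat, pv$sigma2_alpha[pv$trait == tr]))
    if (dominance) {
      add_row("press", "vc_delta",
              press(fit$vc$V_delta[tr, tr], pv$sigma2_delta[pv$trait == tr]))
    }
    ghat_for_h2 <- if (dominance) g_hat else a_hat
    add_row("h2_hat", if (dominance) "total" else "additive",
            estimated_heritability(ghat_for_h2[keep], y[keep]))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gblup_eval", class(out))
  out
}

#' @export
autoplot.gblup_eval <- function(object, statistic = "r_gg", ...) {
  dat <- dplyr::filter(object, .data$statistic == !!statistic)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$trait, y = .data$value,
                                    fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = statistic) +
    ggplot2::theme_minimal()
}

#' k-fold cross-validation of a GBLUP variant
#'
#' Individuals are partitioned into `k` seeded folds. For each fold, all
#' trait records of the held-out individuals are masked, the model is
#' refitted (variance components re-estimated by EM-REML, warm-started at
#' the full-data estimates), and the masked phenotypes are predicted as
#' \eqn{\hat\beta + \hat\alpha + \hat\delta}. The summary reports, per
#' trait, the mean and standard deviation over folds of the Pearson
#' correlation between predicted and observed values.
#'
#' @inheritParams fit_gblup
#' @param k Number of folds (2 to n).
#' @param seed Integer seed for the fold partition.
#' @param fold_max_iter EM iteration cap for the per-fold refits (default
#'   `max_iter`); warm-started fold refits need far fewer iterations than
#'   the full-data fit.
#' @param refit_vc Re-estimate variance components within each fold
#'   (default `TRUE`); `FALSE` reuses the full-data estimates and only
#'   re-solves the MME.
#' @param warm_start Start fold EM at the full-data estimates (default
#'   `TRUE`; the converged optimum does not depend on the start).
#' @return Object of class `"gblup_cv"`: a list with `summary` (tibble:
#'   `trait`, `mean_corr`, `sd_corr`, `k`), `folds` (per-fold
#'   correlations), `predictions`, and the full-data `fit`.
#' @export
kfold_cv <- function(data, A, D = NULL,
                     variant = c("MV-AD", "MV-A", "UV-AD", "UV-A"),
                     traits = NULL, id_col = 1L, k = 10L, seed = NULL,
                     tol = 1e-6, max_iter = 500L, fold_max_iter = max_iter,
                     refit_vc = TRUE, warm_start = TRUE) {
  variant <- match.arg(variant, MODEL_VARIANTS[c(4L, 3L, 2L, 1L)])
  data <- as.data.frame(data)
  ids <- as.character(data[[id_col]])
  n <- length(ids)
  if (k < 2L || k > n) {
    abort("`k` must lie between 2 and the number of individuals.")
  }

  full_fit <- fit_gblup(data, A, D, variant = variant, traits = traits,
                        id_col = id_col, tol = tol, max_iter = max_iter)
  traits <- full_fit$traits
  init <- if (warm_start) full_fit$vc else NULL

  fold_of <- with_seed(seed, {
    sample(rep_len(seq_len(k), n))
  })

  preds <- list()
  fold_rows <- list()
  for (f in seq_len(k)) {
    test_ids <- ids[fold_of == f]
    masked <- data
    masked[ids %in% test_ids, traits] <- NA
    fit_f <- if (refit_vc) {
      fit_gblup(masked, A, D, variant = variant, traits = traits,
                id_col = id_col, init = init, tol = tol,
                max_iter = fold_max_iter)
    } else {
      fit_gblup(masked, A, D, variant = variant, traits = traits,
                id_col = id_col, init = full_fit$vc, tol = tol, max_iter = 0L)
    }
    pr <- predict.gblup_fit(fit_f, ids = test_ids)
    for (tr in traits) {
      y_obs <- data[[tr]][match(test_ids, ids)]
      y_hat <- pr$y_hat[pr$trait == tr][match(test_ids, pr$id[pr$trait == tr])]
      keep <- !is.na(y_obs)
      corr <- if (sum(keep) >= 3L && sd(y_obs[keep]) > 0 && sd(y_hat[keep]) > 0) {
        cor(y_obs[keep], y_hat[keep])
      } else {
        warn(sprintf("Fold %d, trait %s: degenerate observed values; fold skipped.", f, tr))
        NA_real_
      }
      fold_rows[[length(fold_rows) + 1L]] <- tibble::tibble(
        fold = f, trait = tr, corr = corr, n_test = sum(keep)
      )
    }
    pr$fold <- f
    preds[[f]] <- pr
  }
  folds <- dplyr::bind_rows(fold_rows)
  summary <- folds |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(
      mean_corr = mean(.data$corr, na.rm = TRUE),
      sd_corr = sd(.data$corr, na.rm = TRUE),
      k = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$trait, traits))
  structure(
    list(summary = summary, folds = folds,
         predictions = dplyr::bind_rows(preds), fit = full_fit,
         variant = variant, k = k, seed = seed, fold_of = stats::setNames(fold_of, ids)),
    class = "gblup_cv"
  )
}

#' @export
print.gblup_cv <- function(x, ...) {
  cat(sprintf("<gblup_cv> %s, %d-fold\n", x$variant, x$k))
  print(x$summary)
  invisible(x)
}

#' @export
autoplot.gblup_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = .data$trait, y = .data$corr)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(
      x = NULL, y = "fold-wise predicted vs observed correlation",
      title = sprintf("%d-fold cross-validation (%s)", object$k, object$variant)
    ) +
    ggplot2::theme_minimal()
}
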