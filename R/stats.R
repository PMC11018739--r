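#' Pooled-variance unpaired t-test from summary statistics or raw samples
#'
#' Two-sided two-sample t-test with pooled variance, computable from group
#' summary statistics (n, mean, sd) so that printed cohort tables can be
#' checked directly; `unpaired_t_raw()` reduces raw samples to the same
#' summaries, so the two forms agree exactly.
#'
#' @param n1,m1,sd1,n2,m2,sd2 group sizes, means and standard deviations
#'   (`n >= 2`, `sd > 0`).
#' @return object of class `group_comparison`: `statistic` (t), `p_value`,
#'   `df`, `test_name`, `group_summaries`.
#' @export
unpaired_t <- function(n1, m1, sd1, n2, m2, sd2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("need sd > 0 in both groups", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(statistic = tstat, p_value = p, df = df,
                 test_name = "unpaired_t",
                 group_summaries = data.frame(n = c(n1, n2), mean = c(m1, m2),
                                              sd = c(sd1, sd2))),
            class = "group_comparison")
}

#' @rdname unpaired_t
#' @param x,y raw numeric samples.
#' @export
unpaired_t_raw <- function(x, y) {
  unpaired_t(length(x), mean(x), stats::sd(x), length(y), mean(y), stats::sd(y))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration (via
#' `stats::fisher.test`); an empty margin returns p = 1 with a warning.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return object of class `group_comparison` with the odds-ratio estimate
#'   as `statistic`.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L) || any(tab < 0) || any(tab != round(tab)))
    stop("tab must be a 2x2 table of nonnegative integers", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin: p = 1 by convention", call. = FALSE)
    return(structure(list(statistic = NA_real_, p_value = 1,
                          test_name = "fisher_exact", group_summaries = tab),
                     class = "group_comparison"))
  }
  ft <- stats::fisher.test(tab)
  structure(list(statistic = unname(ft$estimate), p_value = ft$p.value,
                 test_name = "fisher_exact", group_summaries = tab),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic=%.4g p=%.4g\n",
              x$test_name, x$statistic, x$p_value))
  invisible(x)
}

#' Two-level mixed-effects logistic regression
#'
#' Random-intercept logistic model with eyes (level 1) nested in subjects
#' (level 2), fitted by Laplace-approximate maximum likelihood through
#' `lme4::glmer`. The default pipeline analysis takes the point-in-zone
#' indicator (zone points vs control-eye points) as outcome and point
#' sensitivity (dB) as predictor, optionally adjusted for the level-2
#' covariates age and sex, so coefficients exponentiate to per-dB odds
#' ratios.
#'
#' @param data data.frame of point-level records.
#' @param outcome name of the binary outcome column.
#' @param predictors character vector of fixed-effect column names.
#' @param subject name of the subject grouping column.
#' @return object of class `mixed_model_fit`: `coefficients` (beta),
#'   `odds_ratios` (exp beta), `ci95` (Wald), `se`, `p_values`,
#'   `random_intercept_sd`, `converged`, `n_obs`, and the underlying `fit`.
#' @export
fit_two_level_logistic <- function(data, outcome, predictors, subject) {
  stopifnot(is.data.frame(data), outcome %in% names(data),
            all(predictors %in% names(data)), subject %in% names(data))
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1, FALSE, TRUE)))
    stop("outcome must be binary", call. = FALSE)
  if (length(unique(data[[subject]])) < 2L)
    stop("need >= 2 subjects", call. = FALSE)
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(predictors, collapse = " + "),
                                 "+ (1 |", subject, ")"))
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(fml, data = data, family = stats::binomial(), nAGQ = 1L)))
  beta <- lme4::fixef(fit)
  se <- suppressWarnings(sqrt(diag(as.matrix(stats::vcov(fit)))))
  ci <- cbind(low = beta - 1.96 * se, high = beta + 1.96 * se)
  p <- 2 * stats::pnorm(-abs(beta / se))
  ri_sd <- sqrt(unname(lme4::VarCorr(fit)[[subject]][1, 1]))
  # optimizer termination plus a direct check of the scaled gradient; huge
  # coefficients or standard errors indicate separation and are flagged too
  dd <- fit@optinfo$derivs
  scgrad <- if (!is.null(dd$gradient) && !is.null(dd$Hessian))
    tryCatch(max(abs(solve(chol(dd$Hessian), dd$gradient))),
             error = function(e) Inf) else 0
  converged <- isTRUE(fit@optinfo$conv$opt == 0) && scgrad < 0.05 &&
    all(is.finite(se)) && all(se < 100) && all(abs(beta) < 15)
  structure(list(coefficients = beta, odds_ratios = exp(beta),
                 ci95 = ci, se = se, p_values = p,
                 random_intercept_sd = ri_sd, converged = converged,
                 n_obs = nrow(data), fit = fit),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("<mixed_model_fit> n=%d, RI sd=%.3f, converged=%s\n",
              x$n_obs, x$random_intercept_sd, x$converged))
  tab <- data.frame(beta = x$coefficients, OR = x$odds_ratios,
                    low = exp(x$ci95[, 1]), high = exp(x$ci95[, 2]),
                    p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Forest table and plot of zone odds ratios
#'
#' Assembles unadjusted and adjusted per-zone odds ratios (with Wald 95% CI
#' and p-values) into a tidy table, one row per zone label in the
#' conventional reporting order, and a forest plot.
#'
#' @param univariable,multivariable named lists of [fit_two_level_logistic()]
#'   fits, one per zone label; coefficients are read from `coef_name`.
#' @param labels zone labels, in display order; must name fits present in
#'   both lists.
#' @param coef_name coefficient reported per fit.
#' @return list with `table` (data.frame) and `plot` (a ggplot object).
#' @export
forest_table <- function(univariable, multivariable = NULL,
                         labels = names(univariable),
                         coef_name = "sensitivity_db") {
  if (!length(univariable)) stop("need at least one fit", call. = FALSE)
  missing_lab <- setdiff(labels, names(univariable))
  if (length(missing_lab))
    stop("no fit for label(s): ", paste(missing_lab, collapse = ", "),
         call. = FALSE)
  row_of <- function(fit, lab, adjusted) {
    if (is.null(fit)) return(NULL)
    i <- match(coef_name, names(fit$coefficients))
    if (is.na(i)) stop("coefficient '", coef_name, "' absent from fit for ",
                       lab, call. = FALSE)
    data.frame(zone = lab, analysis = if (adjusted) "multivariable" else
      "univariable", or = fit$odds_ratios[i],
      ci_low = exp(fit$ci95[i, 1]), ci_high = exp(fit$ci95[i, 2]),
      p_value = fit$p_values[i], converged = fit$converged)
  }
  tab <- do.call(rbind, c(
    lapply(labels, function(l) row_of(univariable[[l]], l, FALSE)),
    lapply(labels, function(l) row_of(multivariable[[l]], l, TRUE))))
  rownames(tab) <- NULL
  tab$zone <- factor(tab$zone, levels = rev(labels))
  plt <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$or, y = .data$zone)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::facet_wrap(~analysis) +
    ggplot2::labs(x = "Odds ratio (per dB of retinal sensitivity)", y = NULL) +
    ggplot2::theme_minimal()
  list(table = tab, plot = plt)
}
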