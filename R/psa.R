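#' Parameter specifications for the probabilistic sensitivity analysis
#'
#' Builds the PSA parameter table from an adjusted cost table: for each
#' condition and loss measure, the adjusted excess loss (point estimate and
#' regression SE, sampled from a normal distribution) and the prevalence
#' (point estimate and binomial SE, sampled from a moment-matched beta
#' distribution). The salary is held fixed.
#'
#' @param adjusted An [adjusted_cost_table()] result (needs columns
#'   `condition`, `measure`, `prevalence`, `adjusted_excess`, and `se`; a
#'   table without an `se` column, such as [printed_adjusted_costs()],
#'   gets zero excess SEs).
#' @param n Sample size behind the prevalence estimates, used for their
#'   binomial SE.
#' @return A tibble with columns `condition`, `measure`, `prevalence`,
#'   `prevalence_se`, `excess`, `excess_se`.
#' @export
psa_parameters <- function(adjusted, n) {
  needed <- c("condition", "measure", "prevalence", "adjusted_excess")
  missing_cols <- setdiff(needed, names(adjusted))
  if (length(missing_cols) > 0) {
    abort(paste0("`adjusted` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  p <- adjusted$prevalence / 100
  tibble(condition = adjusted$condition,
         measure = adjusted$measure,
         prevalence = adjusted$prevalence,
         prevalence_se = 100 * sqrt(p * (1 - p) / n),
         excess = adjusted$adjusted_excess,
         excess_se = if ("se" %in% names(adjusted)) adjusted$se else 0)
}

draw_beta_prevalence <- function(n_sims, p_pct, se_pct) {
  p <- p_pct / 100
  se <- se_pct / 100
  if (se == 0 || p <= 0 || p >= 1) return(rep(p_pct, n_sims))
  v <- se^2
  if (v >= p * (1 - p)) {
    abort("prevalence SE too large for a beta distribution")
  }
  k <- p * (1 - p) / v - 1
  100 * rbeta(n_sims, p * k, (1 - p) * k)
}

#' Monte-Carlo probabilistic sensitivity analysis of the cost model
#'
#' Propagates parameter uncertainty through the per-1000-worker costing:
#' each simulation draws every adjusted excess loss from
#' `normal(point, SE)` and every prevalence from a moment-matched beta,
#' recomputes each condition's annual cost and the per-measure total, and
#' summarises the draws by their mean and the 2.5th/97.5th percentile
#' certainty interval. The contributing-condition set for each measure is
#' fixed by the sign of the *point* estimate (a condition with no excess
#' loss at the point estimate stays excluded in every draw); individual
#' draws may go negative unless `clamp_negative = TRUE`, keeping the
#' Monte-Carlo mean unbiased.
#'
#' @param params Parameter table from [psa_parameters()] (or built by hand
#'   with the same columns). All SEs must be >= 0.
#' @param salary A [salary_model()] (held fixed across draws).
#' @param n_sims Number of Monte-Carlo simulations. Default 1000.
#' @param seed Integer seed for reproducibility; `NULL` uses the current
#'   RNG state.
#' @param n_workers Workforce size to scale to. Default 1000.
#' @param clamp_negative If `TRUE`, negative per-draw total costs are set
#'   to zero (introduces upward bias; off by default).
#' @return An object of class `"psa_result"`: list with `draws` (tibble
#'   `measure`, `sim`, `cost`), `summary` (tibble `measure`, `mean`,
#'   `ci_low`, `ci_high`), `n_sims`. Methods: [autoplot()], [print()].
#' @export
#' @examples
#' params <- psa_parameters(printed_adjusted_costs(), n = 216)
#' psa <- run_psa(params, n_sims = 200, seed = 1)
#' psa$summary
run_psa <- function(params, salary = salary_model(), n_sims = 1000,
                    seed = NULL, n_workers = 1000, clamp_negative = FALSE) {
  needed <- c("condition", "measure", "prevalence", "prevalence_se",
              "excess", "excess_se")
  missing_cols <- setdiff(needed, names(params))
  if (length(missing_cols) > 0) {
    abort(paste0("`params` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (n_sims < 1) abort("`n_sims` must be at least 1")
  if (any(params$excess_se < 0) || any(params$prevalence_se < 0)) {
    abort("SEs must be non-negative")
  }
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  measures <- unique(params$measure)
  draws <- purrr::map_dfr(measures, function(m) {
    rows <- params[params$measure == m & !is.na(params$excess) &
                     params$excess > 0, ]
    if (nrow(rows) == 0) {
      abort(paste0("no contributing conditions for measure ", m))
    }
    total <- numeric(n_sims)
    for (i in seq_len(nrow(rows))) {
      exc <- rnorm(n_sims, rows$excess[i], rows$excess_se[i])
      prev <- draw_beta_prevalence(n_sims, rows$prevalence[i],
                                   rows$prevalence_se[i])
      total <- total + prev / 100 * exc / 100 *
        salary$annual_salary * n_workers
    }
    if (clamp_negative) total <- pmax(total, 0)
    tibble(measure = m, sim = seq_len(n_sims), cost = total)
  })
  summary <- draws |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(mean = mean(.data$cost),
                     ci_low = unname(quantile(.data$cost, 0.025)),
                     ci_high = unname(quantile(.data$cost, 0.975)),
                     .groups = "drop")
  structure(list(draws = draws, summary = summary, n_sims = n_sims,
                 clamp_negative = clamp_negative),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("Probabilistic sensitivity analysis,", x$n_sims, "simulations\n")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.psa_result <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$sim, y = .data$cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(
      data = object$summary,
      ggplot2::aes(yintercept = .data$mean), linetype = "dashed") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "simulation", y = "annual cost per 1000 workers (AUD)",
                  title = "Probabilistic sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Export PSA draws, summary and scatter plot
#'
#' Writes the raw draws as CSV, the summary (mean and 95% certainty
#' interval per measure) as JSON, and the scatter plot to an image file.
#'
#' @param result A [run_psa()] result.
#' @param dir Output directory (created if needed).
#' @param basename File stem for the three outputs. Default `"psa"`.
#' @param plot_format Image format for the scatter (`"pdf"` or `"png"`).
#' @return Invisibly, the paths written.
#' @export
export_psa <- function(result, dir, basename = "psa",
                       plot_format = c("pdf", "png")) {
  stopifnot(inherits(result, "psa_result"))
  plot_format <- match.arg(plot_format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  draws_path <- file.path(dir, paste0(basename, "_draws.csv"))
  summary_path <- file.path(dir, paste0(basename, "_summary.json"))
  plot_path <- file.path(dir, paste0(basename, "_scatter.", plot_format))
  readr::write_csv(result$draws, draws_path)
  jsonlite::write_json(result$summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  ggplot2::ggsave(plot_path, autoplot(result), width = 8, height = 5)
  invisible(c(draws = draws_path, summary = summary_path, plot = plot_path))
}
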