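#' Mann-Whitney test of a high-risk vs low-risk loss difference
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test using the tie-corrected
#' normal approximation. The sign convention follows the applied costing
#' literature: `z < 0` when the high-risk group is stochastically larger
#' (reports more loss).
#'
#' @param high,low Numeric loss values for the high- and low-risk groups.
#' @return A one-row tibble: `n_high`, `n_low`, `u_high` (Mann-Whitney U for
#'   the high group), `z`, `p_value`.
#' @export
#' @examples
#' mann_whitney(c(5, 7, 9), c(1, 2, 3))
mann_whitney <- function(high, low) {
  high <- high[!is.na(high)]
  low <- low[!is.na(low)]
  n1 <- length(high)
  n2 <- length(low)
  if (n1 == 0 || n2 == 0) abort("both groups must be non-empty")
  r <- rank(c(high, low))
  r_high <- sum(r[seq_len(n1)])
  u_high <- r_high - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(c(high, low))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) {
    z <- 0
  } else {
    z <- (u_high - n1 * n2 / 2) / sqrt(v)
  }
  # flip so that a stochastically larger high group reports z < 0
  z <- -z
  tibble(n_high = n1, n_low = n2, u_high = u_high, z = z,
         p_value = min(1, 2 * pnorm(-abs(z))))
}

#' Kruskal-Wallis test across multiple-risk tiers
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference on k - 1
#' degrees of freedom (wraps [stats::kruskal.test()]).
#'
#' @param values Numeric outcome values.
#' @param groups Grouping vector (factor or character) of the same length.
#' @return A one-row tibble: `h`, `df`, `p_value`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b", "c"), each = 2))
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups[!is.na(values)])
  values <- values[!is.na(values)]
  if (nlevels(groups) < 2) abort("need at least 2 non-empty groups")
  kt <- kruskal.test(values, groups)
  tibble(h = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value)
}

#' Dunn's post-hoc pairwise comparisons with Bonferroni adjustment
#'
#' Pairwise z tests on mean ranks following a Kruskal-Wallis test, with the
#' tie-corrected pooled variance; p-values are multiplied by the number of
#' pairs k(k-1)/2 and capped at 1. `z > 0` means the first group of the pair
#' has the larger mean rank.
#'
#' @inheritParams kruskal_wallis
#' @return A tibble with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @export
#' @examples
#' dunn_bonferroni(c(1, 2, 3, 4, 8, 9), rep(c("low", "medium", "high"), each = 2))
dunn_bonferroni <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups[!is.na(values)])
  values <- values[!is.na(values)]
  k <- nlevels(groups)
  if (k < 2) abort("need at least 2 non-empty groups")
  n <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  sizes <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pooled <- n * (n + 1) / 12 - tie_corr
  pairs <- utils::combn(levels(groups), 2)
  n_pairs <- ncol(pairs)
  purrr::map_dfr(seq_len(n_pairs), function(i) {
    g1 <- pairs[1, i]
    g2 <- pairs[2, i]
    se <- sqrt(pooled * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    z <- if (se > 0) (mean_ranks[[g1]] - mean_ranks[[g2]]) / se else 0
    p <- 2 * pnorm(-abs(z))
    tibble(group1 = g1, group2 = g2, z = z, p_value = p,
           p_adjusted = min(1, p * n_pairs))
  })
}

#' Variance inflation factors
#'
#' For each column j of a numeric design matrix, `VIF_j = 1 / (1 - R2_j)`
#' where `R2_j` is from regressing column j on the remaining columns (with
#' intercept). A column perfectly explained by the others (rank deficiency)
#' is flagged with an infinite VIF.
#'
#' @param x Numeric matrix or data frame of predictors (no intercept
#'   column); constant columns are an error.
#' @return Named numeric vector of VIFs, all >= 1 (or `Inf`).
#' @export
#' @examples
#' x <- matrix(rnorm(200), ncol = 2)
#' vif(x)
vif <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) abort("`x` must be numeric")
  if (ncol(x) < 2) abort("need at least 2 columns to compute VIFs")
  if (any(apply(x, 2, sd) == 0)) abort("`x` has constant columns")
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("x", seq_len(ncol(x)))
  out <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, nms)
}

#' Compare loss measures across multiple-risk tiers
#'
#' Per-tier means, the Kruskal-Wallis omnibus test, and Dunn's pairwise
#' comparisons with Bonferroni adjustment for each loss measure.
#'
#' @inheritParams excess_cost_table
#' @return A list with tibbles `tier_means` (measure x tier mean/sd/n),
#'   `kruskal` (one row per measure) and `dunn` (pairwise rows per measure).
#' @export
tier_comparison <- function(profiles, losses) {
  data <- dplyr::inner_join(
    dplyr::filter(profiles, !.data$incomplete), losses, by = "worker_id")
  if (nrow(data) == 0) abort("no complete workers with defined losses")
  tier_means <- purrr::map_dfr(loss_measures(), function(m) {
    data |>
      dplyr::group_by(tier = .data$risk_tier) |>
      dplyr::summarise(mean = mean(.data[[loss_column(m)]]),
                       sd = sd(.data[[loss_column(m)]]),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(measure = m, .before = 1)
  })
  kruskal <- purrr::map_dfr(loss_measures(), function(m) {
    dplyr::mutate(kruskal_wallis(data[[loss_column(m)]], data$risk_tier),
                  measure = m, .before = 1)
  })
  dunn <- purrr::map_dfr(loss_measures(), function(m) {
    dplyr::mutate(dunn_bonferroni(data[[loss_column(m)]], data$risk_tier),
                  measure = m, .before = 1)
  })
  list(tier_means = tier_means, kruskal = kruskal, dunn = dunn)
}
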