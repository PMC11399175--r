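# Pairwise post hoc procedures paired with each omnibus branch:
# Tukey's HSD (classical ANOVA), Games-Howell (Welch), Dunn with
# Bonferroni correction (Kruskal-Wallis). All return the same tibble shape:
# one row per unordered group pair, k(k-1)/2 rows total.

pairwise_skeleton <- function(levels) {
  pairs <- utils::combn(levels, 2L)
  tibble::tibble(group1 = pairs[1L, ], group2 = pairs[2L, ])
}

#' Tukey's honestly-significant-difference post hoc test
#'
#' All pairwise mean comparisons after a classical one-way ANOVA, using the
#' pooled within-group variance and the studentized-range distribution
#' (Tukey-Kramer standard errors for unbalanced designs).
#'
#' @inheritParams assess_normality
#' @param alpha Level for the `significant` flag (default 0.05).
#' @return Tibble with one row per pair: `group1`, `group2`, `estimate`
#'   (mean of `group2` minus mean of `group1`), `se`, `statistic` (q),
#'   `df`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(values, group, alpha = 0.05) {
  d <- drop_missing_pairs(values, group)
  g <- factor(d$group)
  k <- nlevels(g)
  means <- tapply(d$values, g, mean)
  ns <- tapply(d$values, g, length)
  n_total <- length(d$values)
  df2 <- n_total - k
  msw <- sum(tapply(d$values, g, function(v) sum((v - mean(v))^2))) / df2
  out <- pairwise_skeleton(levels(g))
  est <- means[out$group2] - means[out$group1]
  se <- sqrt(msw / 2 * (1 / ns[out$group1] + 1 / ns[out$group2]))
  q <- ifelse(est == 0, 0, abs(est) / se)
  p <- ifelse(se == 0, ifelse(est == 0, 1, 0),
              stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE))
  p[est == 0] <- 1
  dplyr::mutate(out, estimate = as.numeric(est), se = as.numeric(se),
                statistic = as.numeric(q), df = df2, p_adj = as.numeric(p),
                significant = as.logical(p < alpha))
}

#' Games-Howell post hoc test
#'
#' Pairwise comparisons after Welch's ANOVA, for unequal group variances:
#' per pair the statistic
#' \deqn{q = |\bar x_i - \bar x_j| \big/ \sqrt{(s_i^2/n_i + s_j^2/n_j)/2}}
#' is referred to the studentized-range distribution with
#' Welch-Satterthwaite degrees of freedom computed per pair.
#'
#' @inheritParams tukey_hsd
#' @return Tibble as in [tukey_hsd()], with a per-pair real-valued `df`.
#' @export
games_howell <- function(values, group, alpha = 0.05) {
  d <- drop_missing_pairs(values, group)
  g <- factor(d$group)
  k <- nlevels(g)
  means <- tapply(d$values, g, mean)
  vars <- tapply(d$values, g, stats::var)
  ns <- tapply(d$values, g, length)
  if (any(ns < 2L)) {
    stop("Games-Howell requires n >= 2 in every group", call. = FALSE)
  }
  out <- pairwise_skeleton(levels(g))
  vi <- vars[out$group1] / ns[out$group1]
  vj <- vars[out$group2] / ns[out$group2]
  if (any(vi + vj == 0)) {
    bad <- which(vi + vj == 0)[1]
    stop("Games-Howell undefined for zero-variance pair ",
         out$group1[bad], " vs ", out$group2[bad], call. = FALSE)
  }
  est <- means[out$group2] - means[out$group1]
  se <- sqrt((vi + vj) / 2)
  df <- (vi + vj)^2 / (vi^2 / (ns[out$group1] - 1) +
                         vj^2 / (ns[out$group2] - 1))
  q <- abs(est) / se
  p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
  dplyr::mutate(out, estimate = as.numeric(est), se = as.numeric(se),
                statistic = as.numeric(q), df = as.numeric(df), p_adj = as.numeric(p),
                significant = as.logical(p < alpha))
}

#' Dunn's post hoc test with Bonferroni correction
#'
#' Pairwise comparisons after a Kruskal-Wallis test: z statistics from
#' mean-rank differences with the tie-corrected variance
#' \deqn{\mathrm{Var} = \left(\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3 - t)}{12 (N - 1)}\right)
#'   \left(\frac{1}{n_i} + \frac{1}{n_j}\right),}
#' two-sided p-values multiplied by the number of pairs and capped at 1.
#'
#' @inheritParams tukey_hsd
#' @return Tibble with one row per pair: `group1`, `group2`, `estimate`
#'   (mean rank of `group2` minus mean rank of `group1`), `se`,
#'   `statistic` (z), `p_adj` (Bonferroni-adjusted, capped at 1),
#'   `significant`.
#' @export
dunn_bonferroni <- function(values, group, alpha = 0.05) {
  d <- drop_missing_pairs(values, group)
  g <- factor(d$group)
  n_total <- length(d$values)
  rk <- rank(d$values)
  mean_ranks <- tapply(rk, g, mean)
  ns <- tapply(rk, g, length)
  ties <- base::table(d$values)
  tie_sum <- sum(ties^3 - ties)
  var_base <- n_total * (n_total + 1) / 12 -
    tie_sum / (12 * (n_total - 1))
  out <- pairwise_skeleton(levels(g))
  est <- mean_ranks[out$group2] - mean_ranks[out$group1]
  se <- sqrt(var_base * (1 / ns[out$group1] + 1 / ns[out$group2]))
  z <- ifelse(se == 0, 0, est / se)
  m <- nrow(out)
  p <- pmin(1, 2 * stats::pnorm(-abs(z)) * m)
  dplyr::mutate(out, estimate = as.numeric(est), se = as.numeric(se),
                statistic = as.numeric(z), p_adj = as.numeric(p),
                significant = as.logical(p < alpha))
}
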