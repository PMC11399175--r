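# Assumption-driven group comparison: Shapiro-Wilk normality cascade
# (raw -> sqrt -> ln), Levene's homogeneity test, omnibus selection
# (one-way ANOVA / Welch ANOVA / Kruskal-Wallis) and effect sizes.
# Post hoc machinery lives in posthoc.R.

drop_missing_pairs <- function(values, group) {
  keep <- !is.na(values) & !is.na(group)
  list(values = values[keep], group = as.character(group[keep]))
}

#' Per-group Shapiro-Wilk normality assessment
#'
#' Applies the Shapiro-Wilk test within each group at level `alpha`. The
#' data "conform" to normality only if every testable group passes. Groups
#' with fewer than 3 observations cannot be tested and are flagged
#' untestable (they do not block the overall pass); a constant-valued group
#' is an automatic fail with a degenerate-data flag.
#'
#' @param values Numeric vector of observations.
#' @param group Group label per observation.
#' @param alpha Per-group significance level (default 0.05).
#' @return List with `pass` (logical) and `per_group` (tibble: `group`,
#'   `n`, `statistic`, `p`, `testable`, `degenerate`, `pass`).
#' @export
assess_normality <- function(values, group, alpha = 0.05) {
  d <- drop_missing_pairs(values, group)
  per_group <- lapply(split(d$values, d$group), function(v) {
    n <- length(v)
    if (n < 3L) {
      tibble::tibble(n = n, statistic = NA_real_, p = NA_real_,
                     testable = FALSE, degenerate = FALSE, pass = NA)
    } else if (stats::sd(v) == 0) {
      tibble::tibble(n = n, statistic = NA_real_, p = 0,
                     testable = TRUE, degenerate = TRUE, pass = FALSE)
    } else {
      sw <- stats::shapiro.test(v)
      tibble::tibble(n = n, statistic = unname(sw$statistic),
                     p = sw$p.value, testable = TRUE, degenerate = FALSE,
                     pass = sw$p.value > alpha)
    }
  })
  per_group <- dplyr::bind_rows(per_group, .id = "group")
  testable <- per_group$testable
  list(pass = all(per_group$pass[testable]) && any(testable),
       per_group = per_group)
}

#' Normality transform cascade: none, square root, natural log
#'
#' If the raw data fail per-group Shapiro-Wilk normality, the values are
#' square-root transformed and retested; if they still fail, natural-log
#' transformed and tested once more. The first transform under which every
#' testable group passes is kept. The square-root branch requires all
#' values >= 0 and the log branch all values > 0; an inapplicable branch is
#' skipped.
#'
#' @inheritParams assess_normality
#' @return List with `values` (transformed, or original when nothing
#'   worked), `transform` (`"none"`, `"sqrt"` or `"ln"` — the transform the
#'   returned values carry, i.e. the last one attempted when all fail),
#'   `normal` (did the final state pass), `normality_raw` and
#'   `normality_final` (the [assess_normality()] results bracketing the
#'   cascade).
#' @export
transform_cascade <- function(values, group, alpha = 0.05) {
  raw <- assess_normality(values, group, alpha)
  if (isTRUE(raw$pass)) {
    return(list(values = values, transform = "none", normal = TRUE,
                normality_raw = raw, normality_final = raw))
  }
  ok <- !is.na(values)
  tried <- list(values = values, transform = "none", normal = FALSE,
                normality_raw = raw, normality_final = raw)
  if (all(values[ok] >= 0)) {
    v <- sqrt(values)
    a <- assess_normality(v, group, alpha)
    tried <- list(values = v, transform = "sqrt", normal = isTRUE(a$pass),
                  normality_raw = raw, normality_final = a)
    if (tried$normal) return(tried)
  }
  if (all(values[ok] > 0)) {
    v <- log(values)
    a <- assess_normality(v, group, alpha)
    tried <- list(values = v, transform = "ln", normal = isTRUE(a$pass),
                  normality_raw = raw, normality_final = a)
    if (tried$normal) return(tried)
  }
  if (!tried$normal && tried$transform == "none") {
    tried$untransformable <- TRUE
  }
  tried
}

#' Levene's test of homogeneity of variance
#'
#' Classical Levene's test (absolute deviations from the group mean;
#' `center = "median"` gives the Brown-Forsythe variant). Groups with fewer
#' than 2 observations are excluded with a warning. Fully degenerate input
#' (every group constant) yields a flagged `p = 1`.
#'
#' @inheritParams assess_normality
#' @param center `"mean"` (classical, default) or `"median"`.
#' @return List with `statistic`, `df1`, `df2`, `p`, `degenerate`.
#' @export
homogeneity <- function(values, group, center = c("mean", "median")) {
  center <- match.arg(center)
  d <- drop_missing_pairs(values, group)
  sizes <- table(d$group)
  if (any(sizes < 2L)) {
    small <- names(sizes)[sizes < 2L]
    warning("excluding group(s) with n < 2 from Levene's test: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(d$group %in% small)
    d <- list(values = d$values[keep], group = d$group[keep])
  }
  if (length(unique(d$group)) < 2L) {
    stop("Levene's test needs at least 2 groups with n >= 2", call. = FALSE)
  }
  centre_fun <- if (center == "mean") mean else stats::median
  if (all(vapply(split(d$values, d$group), stats::sd, 0) == 0)) {
    return(list(statistic = NA_real_, df1 = length(unique(d$group)) - 1L,
                df2 = length(d$values) - length(unique(d$group)),
                p = 1, degenerate = TRUE))
  }
  lt <- car::leveneTest(d$values, factor(d$group), center = centre_fun)
  list(statistic = lt[1, "F value"], df1 = lt[1, "Df"], df2 = lt[2, "Df"],
       p = lt[1, "Pr(>F)"], degenerate = FALSE)
}

#' Classical one-way ANOVA
#'
#' Fixed-effects between/within decomposition with `df1 = k - 1`,
#' `df2 = N - k`.
#'
#' @inheritParams assess_normality
#' @return List with `statistic` (F), `df1`, `df2`, `p`, `n_total`.
#' @export
one_way_anova <- function(values, group) {
  d <- drop_missing_pairs(values, group)
  g <- factor(d$group)
  if (all(vapply(split(d$values, g), stats::sd, 0) == 0)) {
    stop("one-way ANOVA undefined: zero within-group variance in every group",
         call. = FALSE)
  }
  ow <- stats::oneway.test(d$values ~ g, var.equal = TRUE)
  list(statistic = unname(ow$statistic), df1 = unname(ow$parameter[1]),
       df2 = unname(ow$parameter[2]), p = ow$p.value,
       n_total = length(d$values))
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F with the Welch-Satterthwaite (real-valued) denominator degrees
#' of freedom; robust to unequal group variances.
#'
#' @inheritParams assess_normality
#' @return List with `statistic` (Welch F), `df1`, `df2` (adjusted, real),
#'   `p`, `n_total`.
#' @export
welch_anova <- function(values, group) {
  d <- drop_missing_pairs(values, group)
  g <- factor(d$group)
  vars <- vapply(split(d$values, g), stats::var, 0)
  if (any(vars == 0)) {
    stop("Welch ANOVA undefined: zero variance in group(s) ",
         paste(levels(g)[vars == 0], collapse = ", "), call. = FALSE)
  }
  ow <- stats::oneway.test(d$values ~ g, var.equal = FALSE)
  list(statistic = unname(ow$statistic), df1 = unname(ow$parameter[1]),
       df2 = unname(ow$parameter[2]), p = ow$p.value,
       n_total = length(d$values))
}

#' Kruskal-Wallis rank-based omnibus test
#'
#' Rank-based H with the usual tie correction; `df = k - 1`. All-identical
#' input is reported as `H = 0`, `p = 1` with a degeneracy flag rather than
#' an error.
#'
#' @inheritParams assess_normality
#' @return List with `statistic` (H), `df`, `p`, `n_total`, `degenerate`.
#' @export
kruskal_wallis <- function(values, group) {
  d <- drop_missing_pairs(values, group)
  g <- factor(d$group)
  if (length(unique(d$values)) == 1L) {
    return(list(statistic = 0, df = nlevels(g) - 1L, p = 1,
                n_total = length(d$values), degenerate = TRUE))
  }
  kw <- stats::kruskal.test(d$values, g)
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, n_total = length(d$values), degenerate = FALSE)
}

#' Omega-squared effect size from an F statistic
#'
#' \deqn{\omega^2 = \frac{df_1 (F - 1)}{df_1 (F - 1) + N}, \quad
#'       N = df_1 + df_2 + 1.}
#' Negative values occur whenever `F < 1` (the between-group variation falls
#' below its null expectation) and are reported as computed, never clipped.
#'
#' @param f Observed F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return Omega-squared (dimensionless, may be negative).
#' @export
#' @examples
#' omega_squared(13.5, 3, 75)   # 0.322
#' omega_squared(0.114, 3, 76)  # -0.034
omega_squared <- function(f, df1, df2) {
  stopifnot(all(f >= 0), all(df1 >= 1), all(df2 >= 1))
  n <- df1 + df2 + 1
  num <- df1 * (f - 1)
  num / (num + n)
}

#' Epsilon-squared effect size for the Kruskal-Wallis H
#'
#' \deqn{\epsilon^2 = \frac{H (n + 1)}{n^2 - 1} = \frac{H}{n - 1}.}
#' Rank-based, hence invariant to any strictly monotone transform of the
#' data.
#'
#' @param h Kruskal-Wallis H statistic (>= 0).
#' @param n_total Total number of observations (>= 2).
#' @return Epsilon-squared (dimensionless).
#' @export
epsilon_squared <- function(h, n_total) {
  stopifnot(all(h >= 0))
  if (any(n_total < 2)) stop("epsilon_squared needs n_total >= 2", call. = FALSE)
  h / (n_total - 1)
}

#' Compare groups for one biomarker with the full decision tree
#'
#' Executes the assumption-driven comparison used throughout the package:
#' per-group Shapiro-Wilk normality with the sqrt/ln transform cascade;
#' if normality is (eventually) met, Levene's test decides between the
#' classical one-way ANOVA with Tukey's HSD and Welch's ANOVA with the
#' Games-Howell post hoc (both with omega-squared); if normality fails
#' after both transforms, the Kruskal-Wallis test with Dunn-Bonferroni
#' pairwise comparisons and epsilon-squared is run on the original values
#' (rank-based tests are unaffected by the monotone transforms).
#'
#' @param table A `biomarker_table` (or any data frame with `group` and the
#'   biomarker column).
#' @param biomarker Name of the biomarker column to analyse.
#' @param alpha Significance level for the assumption checks and the
#'   post-hoc significance flags (default 0.05).
#' @param levene_center `"mean"` (classical) or `"median"` (Brown-Forsythe).
#' @param posthoc_if_significant If `TRUE`, post hocs are only run when the
#'   omnibus `p < alpha`; by default they are always run.
#' @return A `group_comparison` object: list with `biomarker`,
#'   `statistic_kind` (`"F"`, `"F_welch"` or `"H"`), `statistic`, `df1`,
#'   `df2` (`NA` for H), `n_total`, `p`, `effect_size_kind`, `effect_size`,
#'   `effect_size_approx` (TRUE on the Welch branch, where the omega-squared
#'   formula is applied with nominal dfs), `posthoc` (pairwise tibble or
#'   `NULL`), `trail` (the decision trail: per-group normality before/after,
#'   `transform_applied`, `normality_final`, `levene_p`, `branch`), and
#'   `skipped`/`skip_reason` when the biomarker had insufficient data.
#' @export
compare_groups <- function(table, biomarker, alpha = 0.05,
                           levene_center = c("mean", "median"),
                           posthoc_if_significant = FALSE) {
  levene_center <- match.arg(levene_center)
  if (!biomarker %in% names(table)) {
    stop("no column '", biomarker, "' in table", call. = FALSE)
  }
  d <- drop_missing_pairs(table[[biomarker]], table$group)
  sizes <- base::table(d$group)
  skip <- function(reason) {
    structure(list(biomarker = biomarker, skipped = TRUE,
                   skip_reason = reason), class = "group_comparison")
  }
  if (length(sizes) < 2L) return(skip("fewer than 2 groups with data"))
  if (any(sizes < 2L)) return(skip("a group has fewer than 2 values"))

  casc <- transform_cascade(d$values, d$group, alpha)
  trail <- list(
    normality_raw = casc$normality_raw$per_group,
    transform_applied = casc$transform,
    normality_final = casc$normality_final$per_group,
    normality_final_pass = casc$normal,
    levene_p = NA_real_,
    branch = NA_character_
  )

  run_posthoc <- function(p) !posthoc_if_significant || p < alpha

  if (casc$normal) {
    lev <- homogeneity(casc$values, d$group, center = levene_center)
    trail$levene_p <- lev$p
    if (lev$p >= alpha) {
      trail$branch <- "anova_tukey"
      om <- one_way_anova(casc$values, d$group)
      res <- list(statistic_kind = "F", statistic = om$statistic,
                  df1 = om$df1, df2 = om$df2, n_total = om$n_total,
                  p = om$p,
                  effect_size_kind = "omega2",
                  effect_size = omega_squared(om$statistic, om$df1, om$df2),
                  effect_size_approx = FALSE,
                  posthoc = if (run_posthoc(om$p))
                    tukey_hsd(casc$values, d$group, alpha = alpha))
    } else {
      trail$branch <- "welch_gameshowell"
      om <- welch_anova(casc$values, d$group)
      k <- length(unique(d$group))
      res <- list(statistic_kind = "F_welch", statistic = om$statistic,
                  df1 = om$df1, df2 = om$df2, n_total = om$n_total,
                  p = om$p,
                  effect_size_kind = "omega2",
                  effect_size = omega_squared(om$statistic, k - 1,
                                              om$n_total - k),
                  effect_size_approx = TRUE,
                  posthoc = if (run_posthoc(om$p))
                    games_howell(casc$values, d$group, alpha = alpha))
    }
  } else {
    trail$branch <- "kruskal_dunn"
    om <- kruskal_wallis(d$values, d$group)
    res <- list(statistic_kind = "H", statistic = om$statistic,
                df1 = om$df, df2 = NA_real_, n_total = om$n_total,
                p = om$p,
                effect_size_kind = "epsilon2",
                effect_size = epsilon_squared(om$statistic, om$n_total),
                effect_size_approx = FALSE,
                posthoc = if (run_posthoc(om$p))
                  dunn_bonferroni(d$values, d$group, alpha = alpha))
  }
  structure(c(list(biomarker = biomarker, skipped = FALSE,
                   skip_reason = NA_character_),
              res, list(trail = trail, alpha = alpha)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat("<group_comparison>", x$biomarker, "- skipped:", x$skip_reason, "\n")
    return(invisible(x))
  }
  df_txt <- if (x$statistic_kind == "H") {
    sprintf("df = %g", x$df1)
  } else {
    sprintf("df = (%g, %.4g)", x$df1, x$df2)
  }
  cat(sprintf("<group_comparison> %s\n  branch: %s (transform: %s)\n",
              x$biomarker, x$trail$branch, x$trail$transform_applied))
  cat(sprintf("  %s = %.4g, %s, p = %.4g, %s = %.4g%s\n",
              x$statistic_kind, x$statistic, df_txt, x$p,
              x$effect_size_kind, x$effect_size,
              if (isTRUE(x$effect_size_approx)) " (approx.)" else ""))
  if (!is.null(x$posthoc)) {
    cat(sprintf("  post hoc: %d pairs, %d significant at alpha = %.3g\n",
                nrow(x$posthoc), sum(x$posthoc$significant), x$alpha))
  }
  invisible(x)
}

#' Run the group-comparison engine over every biomarker of a table
#'
#' @inheritParams compare_groups
#' @param biomarkers Columns to analyse (default: every biomarker column).
#' @return A `group_stats_result`: list with `results` (named list of
#'   [compare_groups()] objects), `summary` (one-row-per-biomarker tibble)
#'   and `posthoc` (long pairwise tibble across biomarkers).
#' @export
compare_all_biomarkers <- function(table, biomarkers = biomarker_names(table),
                                   alpha = 0.05,
                                   levene_center = c("mean", "median"),
                                   posthoc_if_significant = FALSE) {
  levene_center <- match.arg(levene_center)
  results <- lapply(biomarkers, function(b) {
    compare_groups(table, b, alpha = alpha, levene_center = levene_center,
                   posthoc_if_significant = posthoc_if_significant)
  })
  names(results) <- biomarkers
  summary <- dplyr::bind_rows(lapply(results, function(r) {
    if (isTRUE(r$skipped)) {
      tibble::tibble(biomarker = r$biomarker, branch = NA_character_,
                     transform = NA_character_, statistic_kind = NA_character_,
                     statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                     n_total = NA_integer_, p = NA_real_,
                     effect_size_kind = NA_character_, effect_size = NA_real_,
                     significant = NA, skipped = TRUE)
    } else {
      tibble::tibble(biomarker = r$biomarker, branch = r$trail$branch,
                     transform = r$trail$transform_applied,
                     statistic_kind = r$statistic_kind,
                     statistic = r$statistic, df1 = r$df1, df2 = r$df2,
                     n_total = as.integer(r$n_total), p = r$p,
                     effect_size_kind = r$effect_size_kind,
                     effect_size = r$effect_size,
                     significant = r$p < alpha, skipped = FALSE)
    }
  }))
  posthoc <- dplyr::bind_rows(lapply(results, function(r) {
    if (isTRUE(r$skipped) || is.null(r$posthoc)) return(NULL)
    dplyr::mutate(r$posthoc, biomarker = r$biomarker, .before = 1)
  }))
  structure(list(results = results, summary = summary, posthoc = posthoc),
            class = "group_stats_result")
}

#' @export
print.group_stats_result <- function(x, ...) {
  cat("<group_stats_result> of", nrow(x$summary), "biomarkers\n")
  print(x$summary)
  invisible(x)
}
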