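# Integrated Biomarker Response version 2 (IBRv2): log-standardised
# per-biomarker deviation indices against a reference group, summed as
# absolute values into one stress score per group. Order-independent by
# construction (unlike the star-plot-area IBRv1).

#' Configuration for an IBRv2 computation
#'
#' @param reference_group Label of the reference (control) group.
#' @param log_mode `"log_ratio_to_reference_mean"` (default; each value is
#'   divided by the reference-group mean before the log, the convention of
#'   the original IBRv2 description) or `"plain_log"`. Both give identical
#'   deviation indices — the reference-mean factor is a per-biomarker
#'   constant that cancels in the standardisation — which the test suite
#'   asserts.
#' @param log_base `"natural"` (default) or `"base10"`; provably irrelevant
#'   to the deviation indices (a common factor cancels in standardisation).
#' @param zero_offset Non-negative constant added to every value before the
#'   log; with the default 0, non-positive values are an error.
#' @return An `ibr_config` list.
#' @export
ibr_config <- function(reference_group,
                       log_mode = c("log_ratio_to_reference_mean",
                                    "plain_log"),
                       log_base = c("natural", "base10"),
                       zero_offset = 0) {
  stopifnot(zero_offset >= 0)
  structure(list(reference_group = as.character(reference_group),
                 log_mode = match.arg(log_mode),
                 log_base = match.arg(log_base),
                 zero_offset = zero_offset),
            class = "ibr_config")
}

#' Log-standardise one biomarker across all animals
#'
#' The IBRv2 standardisation: values are log-transformed (optionally as a
#' ratio to the reference-group mean), then centred and scaled by the mean
#' and standard deviation of the whole data set (all groups pooled; sample
#' SD, n - 1).
#'
#' @param values Numeric vector, one value per animal.
#' @param group Group label per animal.
#' @param config An [ibr_config()].
#' @param biomarker Name used in error messages.
#' @return Numeric vector of Z scores (missing where `values` is missing).
#' @export
standardize_biomarker <- function(values, group, config,
                                  biomarker = "biomarker") {
  ok <- !is.na(values)
  if (any(values[ok] + config$zero_offset <= 0)) {
    bad <- which(ok & values + config$zero_offset <= 0)
    stop("non-positive value(s) for '", biomarker, "' at row(s) ",
         paste(bad, collapse = ", "),
         "; set zero_offset or clean the data", call. = FALSE)
  }
  y <- rep(NA_real_, length(values))
  x <- values + config$zero_offset
  base_fun <- if (config$log_base == "natural") log else log10
  if (config$log_mode == "log_ratio_to_reference_mean") {
    ref <- x[ok & group == config$reference_group]
    if (!length(ref)) {
      stop("reference group '", config$reference_group,
           "' has no data for '", biomarker, "'", call. = FALSE)
    }
    y[ok] <- base_fun(x[ok] / mean(ref))
  } else {
    y[ok] <- base_fun(x[ok])
  }
  s <- stats::sd(y[ok])
  if (!is.finite(s) || s == 0) {
    stop("biomarker '", biomarker,
         "' is constant after the log step; cannot standardise",
         call. = FALSE)
  }
  (y - mean(y[ok])) / s
}

#' Deviation indices of each group from the reference
#'
#' For each group and biomarker, the mean standardised response minus the
#' mean standardised response of the reference group. Positive values mean
#' stimulation relative to the reference, negative inhibition. The
#' reference row is identically zero.
#'
#' @param z Matrix or data frame of Z scores (animals x biomarkers), as from
#'   [standardize_biomarker()].
#' @param group Group label per animal (row).
#' @param reference_group Reference group label.
#' @return Matrix `A` of deviation indices, groups x biomarkers (`NA` where
#'   a group has no data for a biomarker).
#' @export
deviation_indices <- function(z, group, reference_group) {
  z <- as.matrix(z)
  group <- as.character(group)
  if (!reference_group %in% group) {
    stop("reference group '", reference_group, "' not present", call. = FALSE)
  }
  groups <- unique(group)
  gm <- matrix(NA_real_, nrow = length(groups), ncol = ncol(z),
               dimnames = list(groups, colnames(z)))
  for (g in groups) {
    gm[g, ] <- colMeans(z[group == g, , drop = FALSE], na.rm = TRUE)
  }
  gm[is.nan(gm)] <- NA_real_
  ref <- gm[reference_group, ]
  if (any(is.na(ref))) {
    warning("reference group missing data for biomarker(s): ",
            paste(colnames(z)[is.na(ref)], collapse = ", "), call. = FALSE)
  }
  sweep(gm, 2L, ref, "-")
}

#' IBRv2 score of one group
#'
#' The sum of the absolute values of the group's biomarker deviation
#' indices. Missing indices are excluded; the number of contributing
#' biomarkers is reported alongside.
#'
#' @param a Numeric vector of deviation indices for one group.
#' @return List with `score` and `n_biomarkers` (contributing count);
#'   `score` is `NA` when every index is missing.
#' @export
#' @examples
#' ibr_score(c(1.02, 0.063, 0.876, 0.372, 0.224, 0.137, 0.564,
#'             0.461, 0.100, 0.337, 0.001, 0.103, 0.782, 0.199))$score  # 5.24
ibr_score <- function(a) {
  ok <- !is.na(a)
  if (!any(ok)) return(list(score = NA_real_, n_biomarkers = 0L))
  list(score = sum(abs(a[ok])), n_biomarkers = sum(ok))
}

#' Integrated Biomarker Response (IBRv2) of a grouped biomarker table
#'
#' Full IBRv2 computation: per-biomarker log-standardisation across all
#' animals, per-group deviation indices against the reference group, and
#' the per-group score as the sum of absolute deviation indices.
#'
#' @param table A `biomarker_table`.
#' @param config An [ibr_config()], or a reference-group label (a default
#'   config is then built).
#' @param biomarkers Biomarker columns to include (default: all).
#' @return An `ibr_result`: list with `A` (signed deviation matrix, groups
#'   x biomarkers), `abs_A`, `scores` (tibble: `group`, `IBRv2`,
#'   `n_biomarkers`), `config`, `sd_mode = "sample"`.
#' @export
ibr <- function(table, config, biomarkers = biomarker_names(table)) {
  if (!inherits(config, "ibr_config")) config <- ibr_config(config)
  if (!config$reference_group %in% table$group) {
    stop("reference group '", config$reference_group,
         "' not found in table", call. = FALSE)
  }
  z <- sapply(biomarkers, function(b) {
    standardize_biomarker(table[[b]], table$group, config, biomarker = b)
  })
  z <- matrix(z, nrow = nrow(table),
              dimnames = list(table$animal_id, biomarkers))
  a <- deviation_indices(z, table$group, config$reference_group)
  scores <- lapply(rownames(a), function(g) {
    s <- ibr_score(a[g, ])
    tibble::tibble(group = g, IBRv2 = s$score,
                   n_biomarkers = s$n_biomarkers)
  })
  structure(list(A = a, abs_A = abs(a), scores = dplyr::bind_rows(scores),
                 config = config, sd_mode = "sample"),
            class = "ibr_result")
}

#' @export
print.ibr_result <- function(x, ...) {
  cat("<ibr_result> reference:", x$config$reference_group, "\n")
  tab <- cbind(round(x$abs_A, 3), IBRv2 = round(x$scores$IBRv2, 2))
  print(tab)
  invisible(x)
}

#' Radar-plot polygon data from an IBRv2 result
#'
#' Ordered (biomarker, signed deviation) vertices per group, with the
#' biomarker order fixed and identical across groups and a zero baseline
#' ring representing the reference group.
#'
#' @param result An [ibr()] result.
#' @return Tibble with columns `group`, `biomarker` (factor with fixed
#'   level order), `deviation`, `baseline` (0).
#' @export
radar_data <- function(result) {
  stopifnot(inherits(result, "ibr_result"))
  a <- result$A
  tibble::tibble(
    group = rep(rownames(a), each = ncol(a)),
    biomarker = factor(rep(colnames(a), times = nrow(a)),
                       levels = colnames(a)),
    deviation = as.vector(t(a)),
    baseline = 0
  )
}

#' Radar plot of IBRv2 deviation profiles
#'
#' One polar panel per exposure group showing the signed deviation index of
#' each biomarker against the zero ring of the reference group.
#'
#' @param result An [ibr()] result.
#' @param exclude_reference Drop the (all-zero) reference panel
#'   (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_radar <- function(result, exclude_reference = TRUE) {
  rd <- radar_data(result)
  if (exclude_reference) {
    rd <- rd[rd$group != result$config$reference_group, , drop = FALSE]
  }
  ggplot2::ggplot(rd, ggplot2::aes(x = .data$biomarker, y = .data$deviation,
                                   group = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_polygon(fill = NA, colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_polar() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = "Deviation index (A)") +
    ggplot2::theme_minimal()
}
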