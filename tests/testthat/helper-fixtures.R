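# Shared fixture builders: grouped samples with controllable location,
# scale and shape, and small biomarker tables. All randomness goes through
# withr::local_seed so fixtures are frozen.

make_grouped <- function(n_per_group, means, sds = 1, seed = 1,
                         dist = c("normal", "lognormal"),
                         labels = paste0("G", seq_along(means))) {
  dist <- match.arg(dist)
  sds <- rep_len(sds, length(means))
  n_per_group <- rep_len(n_per_group, length(means))
  withr::local_seed(seed)
  values <- unlist(lapply(seq_along(means), function(i) {
    if (dist == "normal") {
      stats::rnorm(n_per_group[i], means[i], sds[i])
    } else {
      stats::rlnorm(n_per_group[i], means[i], sds[i])
    }
  }))
  list(values = values,
       group = rep(labels, times = n_per_group))
}

make_table <- function(n_per_group = 8, n_biomarkers = 3, seed = 1,
                       groups = c("A1", "A2", "A3"), meanlog = 1,
                       sdlog = 0.4) {
  withr::local_seed(seed)
  n <- n_per_group * length(groups)
  tb <- tibble::tibble(
    animal_id = sprintf("fish%02d", seq_len(n)),
    group = rep(groups, each = n_per_group)
  )
  for (b in seq_len(n_biomarkers)) {
    tb[[paste0("bm", b)]] <- stats::rlnorm(n, meanlog, sdlog)
  }
  ibrtox::as_biomarker_table(tb)
}

# Bimodal positive data that no monotone transform can normalise: used to
# force the rank-based branch.
make_bimodal_groups <- function(n_per_group = 20, k = 4, seed = 7) {
  withr::local_seed(seed)
  values <- unlist(lapply(seq_len(k), function(i) {
    half <- n_per_group %/% 2
    c(stats::rnorm(half, 0.1, 0.005),
      stats::rnorm(n_per_group - half, 5, 0.05))
  }))
  list(values = values, group = rep(paste0("G", seq_len(k)),
                                    each = n_per_group))
}
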