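# Synthetic multi-biomarker exposure studies with known ground truth:
# a dilution-series design (control + graded leachate fractions), a
# positive, right-skewed biomarker battery, configurable per-biomarker
# effect directions/sizes, and raw-plate emulation for round-trip tests.

#' Default biomarker battery for synthetic studies
#'
#' Mirrors a typical oxidative-stress + energetics battery: enzyme
#' activities and damage products (positive, right-skewed), energy
#' reserves and consumption. `effect_size` is the shift of the log-scale
#' (lognormal family) or raw-scale (normal family) mean at full exposure
#' strength, in units of the within-group SD on that scale; `direction`
#' says whether exposure stimulates or inhibits the endpoint.
#'
#' @return Tibble with columns `biomarker`, `baseline`, `cv`, `direction`,
#'   `effect_size`.
#' @export
default_biomarker_panel <- function() {
  tibble::tribble(
    ~biomarker,       ~baseline, ~cv,  ~direction,   ~effect_size,
    "AChE",            0.050,    0.30, "inhibited",  1.5,
    "MT",              0.200,    0.30, "none",       0.0,
    "SOD",             0.120,    0.35, "inhibited",  1.5,
    "CAT",             0.800,    0.30, "stimulated", 1.5,
    "GSH",             0.350,    0.30, "stimulated", 1.0,
    "GST",             0.450,    0.25, "inhibited",  1.5,
    "MDA",             0.150,    0.35, "stimulated", 1.5,
    "PC",              0.250,    0.30, "none",       0.0,
    "protein_energy",  30.0,     0.20, "none",       0.0,
    "glucose_energy",  10.0,     0.30, "stimulated", 1.5,
    "lipid_energy",    20.0,     0.25, "none",       0.0,
    "Ec",              12.0,     0.30, "inhibited",  1.0
  )
}

#' Describe a synthetic exposure-study design
#'
#' The default mirrors a 4-tank dilution series — a control plus 25%, 50%
#' and 100% leachate — with 20 animals per group and the
#' [default_biomarker_panel()].
#'
#' @param groups Named numeric vector: group label -> exposure fraction in
#'   `[0, 1]`.
#' @param n_per_group Animals per group (>= 2; recycled across groups).
#' @param biomarkers Tibble as [default_biomarker_panel()].
#' @param family `"lognormal"` (default; positive, right-skewed, effects
#'   shift the log-scale mean so they act multiplicatively on the median)
#'   or `"normal"` (effects shift the mean additively; used to exercise
#'   the parametric analysis branch).
#' @param variance_heterogeneity Optional named numeric vector of per-group
#'   SD multipliers (default all 1).
#' @param dropout Per-group probability that an individual biomarker cell
#'   is missing (default 0; recycled across groups).
#' @param seed Integer seed; the whole study is reproducible from it.
#' @return A `study_design` list.
#' @export
study_design <- function(groups = c(A1 = 0, A2 = 0.25, A3 = 0.5, A4 = 1),
                         n_per_group = 20,
                         biomarkers = default_biomarker_panel(),
                         family = c("lognormal", "normal"),
                         variance_heterogeneity = NULL,
                         dropout = 0,
                         seed = 1L) {
  family <- match.arg(family)
  stopifnot(length(groups) >= 2L, all(groups >= 0), all(groups <= 1),
            !is.null(names(groups)), all(n_per_group >= 2L))
  biomarkers <- tibble::as_tibble(biomarkers)
  stopifnot(all(biomarkers$baseline > 0), all(biomarkers$cv > 0),
            all(biomarkers$direction %in% c("stimulated", "inhibited", "none")))
  if (is.null(variance_heterogeneity)) {
    variance_heterogeneity <- stats::setNames(rep(1, length(groups)),
                                              names(groups))
  }
  stopifnot(all(names(groups) %in% names(variance_heterogeneity)))
  structure(list(groups = groups,
                 n_per_group = rep_len(n_per_group, length(groups)),
                 biomarkers = biomarkers, family = family,
                 variance_heterogeneity = variance_heterogeneity,
                 dropout = rep_len(dropout, length(groups)),
                 seed = as.integer(seed)),
            class = "study_design")
}

direction_sign <- function(direction) {
  c(stimulated = 1, inhibited = -1, none = 0)[direction]
}

#' Generate a synthetic biomarker table from a study design
#'
#' Draws every animal x biomarker value from the configured family. In the
#' lognormal family a biomarker with baseline `m` and coefficient of
#' variation `cv` has log-scale SD `sqrt(log(1 + cv^2))`; the exposure
#' effect shifts the log-scale mean of group `g` by
#' `direction * effect_size * fraction(g)` log-SDs, i.e. acts
#' multiplicatively on the median. In the normal family the shift is
#' `direction * effect_size * fraction(g)` raw SDs (`baseline * cv`).
#' Identical seeds give identical tables.
#'
#' @param design A [study_design()].
#' @return A `biomarker_table` with attribute `"design"`.
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  withr::local_seed(design$seed)
  glabels <- names(design$groups)
  rows <- list()
  for (gi in seq_along(glabels)) {
    g <- glabels[gi]
    n <- design$n_per_group[gi]
    frac <- design$groups[[g]]
    sd_mult <- design$variance_heterogeneity[[g]]
    row <- tibble::tibble(
      animal_id = sprintf("%s_%02d", g, seq_len(n)),
      group = g
    )
    for (bi in seq_len(nrow(design$biomarkers))) {
      bm <- design$biomarkers[bi, ]
      dir_sign <- direction_sign(bm$direction)
      if (design$family == "lognormal") {
        sdlog <- sqrt(log(1 + bm$cv^2))
        mulog <- log(bm$baseline) - sdlog^2 / 2 +
          dir_sign * bm$effect_size * frac * sdlog
        v <- stats::rlnorm(n, meanlog = mulog, sdlog = sdlog * sd_mult)
      } else {
        sd_raw <- bm$baseline * bm$cv
        mu <- bm$baseline + dir_sign * bm$effect_size * frac * sd_raw
        v <- stats::rnorm(n, mean = mu, sd = sd_raw * sd_mult)
        if (any(v <= 0)) {
          stop("normal-family design for '", bm$biomarker,
               "' produced non-positive values; reduce cv or ",
               "effect size, or use the lognormal family", call. = FALSE)
        }
      }
      if (design$dropout[gi] > 0) {
        v[stats::runif(n) < design$dropout[gi]] <- NA_real_
      }
      row[[bm$biomarker]] <- v
    }
    rows[[g]] <- row
  }
  out <- as_biomarker_table(dplyr::bind_rows(rows))
  attr(out, "design") <- design
  out
}

#' Default microplate read schedules for the synthetic battery
#'
#' Kinetic biomarkers carry a read schedule (seconds) and all assays a
#' wavelength, mirroring common practice for this battery (e.g. an
#' acetylcholinesterase-type assay read at 412 nm every minute for 6 min;
#' a dismutase-type assay every 30 s over 4 min at 420 nm).
#'
#' @return Tibble with columns `biomarker`, `kinetic`, `wavelength_nm` and
#'   a `times` list-column (NULL for endpoint assays).
#' @export
assay_schedules <- function() {
  tibble::tibble(
    biomarker = c("AChE", "SOD", "GST", "Ec", "MT", "CAT", "GSH", "MDA",
                  "PC", "protein_energy", "glucose_energy", "lipid_energy"),
    kinetic = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 8)),
    wavelength_nm = c(412, 420, 340, 490, 412, 480, 420, 532, 360, 595,
                      490, 405),
    times = list(seq(0, 360, by = 60), seq(0, 240, by = 30),
                 seq(0, 180, by = 30), seq(0, 300, by = 30),
                 NULL, NULL, NULL, NULL, NULL, NULL, NULL, NULL)
  )
}

#' Emulate raw plate data for one biomarker of a synthetic study
#'
#' Builds long-format plate data (triplicate sample wells plus blank
#' wells) whose reduction through the assay pipeline — kinetic slope,
#' blank correction, replicate aggregation, protein normalisation —
#' recovers the designed per-animal values (exactly when `noise_sd = 0`).
#' Kinetic wells get absorbance ramps at the biomarker's read schedule;
#' endpoint wells a single read. The designed value is interpreted as the
#' protein-normalised endpoint, so each animal's raw well signal is
#' `value * protein + blank`.
#'
#' @param design A [study_design()].
#' @param biomarker Biomarker to emulate.
#' @param table Optional pre-generated table (default
#'   `generate_study(design)`).
#' @param noise_sd SD of per-read Gaussian absorbance noise (OD; default 0).
#' @param blank_value Reagent-only signal (endpoint OD or OD/min; default
#'   0.05).
#' @param protein Per-animal protein content in mg (default: all 2).
#' @param replicates Technical replicates per sample (default 3).
#' @param n_blanks Blank wells (default 3).
#' @return List with `plate` (long tibble: `well`, `sample`, `role`,
#'   `replicate`, `time_s`, `absorbance`, `wavelength_nm`, `assay`),
#'   `protein` (named vector), `truth` (designed per-animal values) and
#'   `kinetic`.
#' @export
generate_plate <- function(design, biomarker, table = NULL, noise_sd = 0,
                           blank_value = 0.05, protein = NULL,
                           replicates = 3L, n_blanks = 3L) {
  stopifnot(inherits(design, "study_design"))
  if (is.null(table)) table <- generate_study(design)
  if (!biomarker %in% names(table)) {
    stop("biomarker '", biomarker, "' not in table", call. = FALSE)
  }
  sched <- assay_schedules()
  si <- match(biomarker, sched$biomarker)
  kinetic <- if (is.na(si)) FALSE else sched$kinetic[si]
  wl <- if (is.na(si)) 405 else sched$wavelength_nm[si]
  times <- if (kinetic) sched$times[[si]] else NA_real_
  truth <- stats::setNames(table[[biomarker]], table$animal_id)
  truth <- truth[!is.na(truth)]
  if (is.null(protein)) {
    protein <- stats::setNames(rep(2, length(truth)), names(truth))
  }
  wells <- list()
  widx <- 0L
  add_well <- function(sample, role, replicate, signal) {
    widx <<- widx + 1L
    well <- sprintf("W%03d", widx)
    if (kinetic) {
      t_min <- times / 60
      ab <- 0.1 + signal * t_min + stats::rnorm(length(times), 0, noise_sd)
      tibble::tibble(well = well, sample = sample, role = role,
                     replicate = replicate, time_s = times, absorbance = ab,
                     wavelength_nm = wl, assay = biomarker)
    } else {
      tibble::tibble(well = well, sample = sample, role = role,
                     replicate = replicate, time_s = NA_real_,
                     absorbance = signal + stats::rnorm(1, 0, noise_sd),
                     wavelength_nm = wl, assay = biomarker)
    }
  }
  for (id in names(truth)) {
    raw <- truth[[id]] * protein[[id]] + blank_value
    for (r in seq_len(replicates)) {
      wells[[length(wells) + 1L]] <- add_well(id, "sample", r, raw)
    }
  }
  for (b in seq_len(n_blanks)) {
    wells[[length(wells) + 1L]] <- add_well(sprintf("blank_%d", b), "blank",
                                            b, blank_value)
  }
  list(plate = dplyr::bind_rows(wells), protein = protein, truth = truth,
       kinetic = kinetic)
}

#' Recover designed per-animal endpoints from emulated plate data
#'
#' Convenience wrapper running [process_plate()] and
#' [normalize_to_protein()] on the output of [generate_plate()].
#'
#' @param plate_bundle The list returned by [generate_plate()].
#' @return Tibble with `sample_id`, `value` (recovered, protein-normalised),
#'   `truth`, `cv`.
#' @export
recover_endpoints <- function(plate_bundle) {
  agg <- process_plate(plate_bundle$plate,
                       assay = plate_bundle$plate$assay[1],
                       kinetic = plate_bundle$kinetic)
  agg$value <- unname(normalize_to_protein(
    agg$value, unname(plate_bundle$protein[agg$sample_id]),
    agg$sample_id))
  agg$truth <- unname(plate_bundle$truth[agg$sample_id])
  agg[, c("sample_id", "value", "truth", "cv")]
}

#' Ground-truth recovery report for a synthetic study analysis
#'
#' Compares the analysis outputs against the design that generated the
#' data: per biomarker, the true effect direction vs the sign of its
#' deviation index at the highest exposure, whether the omnibus test
#' rejected, and the decision-tree branch taken; plus the IBRv2 dose
#' profile and whether it is non-decreasing in exposure fraction.
#'
#' @param design The [study_design()] that generated the data.
#' @param stats_result A [compare_all_biomarkers()] result.
#' @param ibr_result An [ibr()] result.
#' @param alpha Rejection level used for `omnibus_rejected` (default 0.05).
#' @return List with `per_biomarker` (tibble), `ibr_by_dose` (tibble,
#'   ordered by exposure fraction) and `ibr_monotone` (logical).
#' @export
recovery_report <- function(design, stats_result, ibr_result, alpha = 0.05) {
  stopifnot(inherits(design, "study_design"))
  top_group <- names(design$groups)[which.max(design$groups)]
  per_bm <- dplyr::left_join(
    design$biomarkers[, c("biomarker", "direction", "effect_size")],
    stats_result$summary[, c("biomarker", "branch", "statistic_kind",
                             "statistic", "p", "effect_size")],
    by = "biomarker", suffix = c("_true", "_observed")
  )
  a_top <- ibr_result$A[top_group, per_bm$biomarker]
  per_bm$A_top <- unname(a_top)
  per_bm$direction_detected <- dplyr::case_when(
    is.na(a_top) ~ NA_character_,
    a_top > 0 ~ "stimulated",
    a_top < 0 ~ "inhibited",
    TRUE ~ "none"
  )
  per_bm$direction_match <- ifelse(
    per_bm$direction == "none", NA,
    per_bm$direction == per_bm$direction_detected
  )
  per_bm$omnibus_rejected <- per_bm$p < alpha
  doses <- sort(design$groups)
  ibr_by_dose <- dplyr::left_join(
    tibble::tibble(group = names(doses), fraction = unname(doses)),
    ibr_result$scores, by = "group"
  )
  exposed <- ibr_by_dose$fraction > 0
  list(per_biomarker = per_bm, ibr_by_dose = ibr_by_dose,
       ibr_monotone = !is.unsorted(ibr_by_dose$IBRv2[exposed]))
}
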