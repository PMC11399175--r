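# Reduction of raw microplate readings to per-animal biomarker endpoints:
# kinetic slopes, blank correction, replicate aggregation, protein
# normalisation, and assembly of the tidy animal x biomarker table.

#' Construct a kinetic absorbance trace
#'
#' A kinetic trace is the read schedule of one microplate well: optical
#' density recorded at a series of strictly increasing times. Enzyme
#' activities such as acetylcholinesterase (read at 1-min intervals over
#' 6 min at 412 nm) or glutathione S-transferase (every 30 s over 3 min at
#' 340 nm) are quantified as the slope of such a trace.
#'
#' @param well_id Well identifier, e.g. `"A1"`.
#' @param sample_id Sample the well belongs to; blanks keep their own id.
#' @param times Numeric vector of read times in seconds, strictly increasing,
#'   length >= 2.
#' @param absorbances Numeric vector of optical densities, same length as
#'   `times`.
#' @param wavelength Read wavelength in nm (> 0).
#' @param role `"sample"` or `"blank"`.
#'
#' @return An object of class `kinetic_trace`.
#' @export
#' @examples
#' tr <- kinetic_trace("A1", "fish01", times = c(0, 60, 120, 180),
#'                     absorbances = c(0.10, 0.20, 0.30, 0.40),
#'                     wavelength = 412)
#' kinetic_rate(tr)  # 0.10 OD/min
kinetic_trace <- function(well_id, sample_id, times, absorbances,
                          wavelength, role = c("sample", "blank")) {
  role <- match.arg(role)
  times <- as.numeric(times)
  absorbances <- as.numeric(absorbances)
  if (length(times) < 2L) {
    stop("invalid trace in well '", well_id, "': need at least 2 time points",
         call. = FALSE)
  }
  if (length(times) != length(absorbances)) {
    stop("invalid trace in well '", well_id,
         "': times and absorbances differ in length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("invalid trace in well '", well_id,
         "': times must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(absorbances))) {
    stop("invalid trace in well '", well_id, "': non-finite absorbance",
         call. = FALSE)
  }
  if (!is.finite(wavelength) || wavelength <= 0) {
    stop("invalid trace in well '", well_id, "': wavelength must be > 0",
         call. = FALSE)
  }
  structure(
    list(well_id = as.character(well_id), sample_id = as.character(sample_id),
         role = role, times = times, absorbances = absorbances,
         wavelength = as.numeric(wavelength)),
    class = "kinetic_trace"
  )
}

#' Construct a single endpoint absorbance read
#'
#' Endpoint assays (metallothionein, catalase, malondialdehyde, protein
#' carbonyl, reduced glutathione, glucose, lipid, protein) produce one
#' optical density per well rather than a time course.
#'
#' @inheritParams kinetic_trace
#' @param absorbance Optical density, finite.
#'
#' @return An object of class `endpoint_read`.
#' @export
endpoint_read <- function(well_id, sample_id, absorbance, wavelength,
                          role = c("sample", "blank")) {
  role <- match.arg(role)
  if (!is.finite(absorbance)) {
    stop("invalid read in well '", well_id, "': non-finite absorbance",
         call. = FALSE)
  }
  if (!is.finite(wavelength) || wavelength <= 0) {
    stop("invalid read in well '", well_id, "': wavelength must be > 0",
         call. = FALSE)
  }
  structure(
    list(well_id = as.character(well_id), sample_id = as.character(sample_id),
         role = role, absorbance = as.numeric(absorbance),
         wavelength = as.numeric(wavelength)),
    class = "endpoint_read"
  )
}

#' Kinetic reaction rate from an absorbance trace
#'
#' Ordinary least-squares slope of absorbance against time, reported per
#' minute. The sign is preserved: substrate-depletion assays with falling
#' optical density give negative rates. The slope is invariant to a constant
#' baseline shift of the whole trace.
#'
#' @param trace A [kinetic_trace()].
#' @return Slope in OD/minute.
#' @export
kinetic_rate <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t_min <- trace$times / 60
  if (diff(range(t_min)) <= 0) {
    stop("invalid trace in well '", trace$well_id, "': zero time span",
         call. = FALSE)
  }
  tc <- t_min - mean(t_min)
  sum(tc * trace$absorbances) / sum(tc^2)
}

#' Subtract the mean blank signal from sample values
#'
#' Procedural blanks carry the reagent-only signal; the assay signal
#' attributable to the sample is the raw value minus the mean across all
#' blank wells of the run. Works identically for endpoint absorbances and
#' kinetic rates (the mean blank rate is subtracted).
#'
#' @param values Named numeric vector of per-well values (endpoint OD or
#'   OD/min), names are well ids.
#' @param roles Character vector parallel to `values`, each `"sample"` or
#'   `"blank"`.
#' @return A list with `corrected` (named numeric, sample wells only) and
#'   `blank_value` (the mean blank used).
#' @export
blank_correct <- function(values, roles) {
  stopifnot(length(values) == length(roles))
  is_blank <- roles == "blank"
  if (!any(is_blank)) {
    stop("blank correction requires at least one blank well", call. = FALSE)
  }
  blank_value <- mean(values[is_blank])
  list(corrected = values[!is_blank] - blank_value, blank_value = blank_value)
}

#' Aggregate technical replicates to one value per sample
#'
#' Samples are read in triplicate; the per-sample endpoint is the replicate
#' mean. The coefficient of variation (sd/mean) flags unreliable wells: a
#' sample whose CV exceeds `cv_threshold` is marked. A single replicate has
#' an undefined CV, reported as `NA` without a flag.
#'
#' @param values Numeric vector of per-well values (already blank-corrected).
#' @param sample_ids Character vector parallel to `values`.
#' @param cv_threshold CV above which a sample is flagged (default 0.20).
#' @return A tibble with columns `sample_id`, `value`, `cv`, `n_replicates`,
#'   `flagged`.
#' @export
aggregate_replicates <- function(values, sample_ids, cv_threshold = 0.20) {
  stopifnot(length(values) == length(sample_ids))
  tibble::tibble(sample_id = as.character(sample_ids), value = values) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      cv = if (dplyr::n() > 1L && mean(.data$value) != 0) {
        stats::sd(.data$value) / abs(mean(.data$value))
      } else if (dplyr::n() > 1L) {
        NA_real_
      } else {
        NA_real_
      },
      n_replicates = dplyr::n(),
      value = mean(.data$value),
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = !is.na(.data$cv) & .data$cv > cv_threshold) |>
    dplyr::select("sample_id", "value", "cv", "n_replicates", "flagged")
}

#' Normalise an assay endpoint to sample protein content
#'
#' Biomarker endpoints are standardised by the protein content of the
#' homogenate, so values become per-mg-protein and are comparable across
#' animals with different tissue yields.
#'
#' @param raw Numeric vector of per-sample assay values.
#' @param protein Numeric vector of protein content (mg), parallel to `raw`,
#'   all > 0.
#' @param sample_ids Optional ids used in error messages.
#' @return `raw / protein`.
#' @export
normalize_to_protein <- function(raw, protein, sample_ids = NULL) {
  stopifnot(length(raw) == length(protein))
  bad <- !is.na(protein) & protein <= 0
  if (any(bad)) {
    who <- if (is.null(sample_ids)) which(bad) else sample_ids[bad]
    stop("protein content must be > 0 for sample(s): ",
         paste(who, collapse = ", "), call. = FALSE)
  }
  raw / protein
}

#' Assemble the tidy animal-by-biomarker table
#'
#' Joins per-assay, per-sample endpoint values into one wide table with one
#' row per animal, a group label, and one column per biomarker. Animals
#' missing an assay get an explicit `NA`, never a dropped row.
#'
#' @param assay_values Named list: one element per biomarker, each a tibble
#'   or data.frame with columns `sample_id` and `value`.
#' @param groups Tibble/data.frame with columns `animal_id` and `group`
#'   assigning every animal to an exposure group.
#' @param units Optional named character vector of per-biomarker unit
#'   strings, attached as the `"units"` attribute.
#' @return A `biomarker_table`: tibble with columns `animal_id`, `group`,
#'   then one numeric column per biomarker.
#' @export
build_biomarker_table <- function(assay_values, groups, units = NULL) {
  stopifnot(is.list(assay_values), length(assay_values) > 0L,
            !is.null(names(assay_values)))
  groups <- tibble::as_tibble(groups)
  if (anyDuplicated(groups$animal_id)) {
    dup <- unique(groups$animal_id[duplicated(groups$animal_id)])
    stop("duplicate animal_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::mutate(groups,
                       animal_id = as.character(.data$animal_id),
                       group = as.character(.data$group))
  for (bm in names(assay_values)) {
    av <- tibble::as_tibble(assay_values[[bm]])
    if (anyDuplicated(av$sample_id)) {
      stop("duplicate animal_id in assay '", bm, "'", call. = FALSE)
    }
    unknown <- setdiff(as.character(av$sample_id), out$animal_id)
    if (length(unknown)) {
      stop("assay '", bm, "' has sample(s) without a group assignment: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    av <- stats::setNames(av[, c("sample_id", "value")], c("animal_id", bm))
    av$animal_id <- as.character(av$animal_id)
    out <- dplyr::left_join(out, av, by = "animal_id")
  }
  as_biomarker_table(out, units = units)
}

#' Coerce a data frame to a validated biomarker table
#'
#' @param x Data frame with columns `animal_id`, `group` and at least one
#'   numeric biomarker column.
#' @param units Optional named character vector of unit metadata.
#' @return A `biomarker_table` tibble.
#' @export
as_biomarker_table <- function(x, units = NULL) {
  x <- tibble::as_tibble(x)
  need <- c("animal_id", "group")
  if (!all(need %in% names(x))) {
    stop("biomarker table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bm <- setdiff(names(x), need)
  if (!length(bm)) stop("biomarker table has no biomarker columns", call. = FALSE)
  if (length(unique(x$group)) < 2L) {
    stop("biomarker table needs at least 2 groups", call. = FALSE)
  }
  for (b in bm) {
    v <- x[[b]]
    if (!is.numeric(v)) stop("biomarker column '", b, "' is not numeric",
                             call. = FALSE)
    if (any(!is.na(v) & !is.finite(v))) {
      stop("biomarker column '", b, "' contains non-finite values",
           call. = FALSE)
    }
  }
  attr(x, "units") <- units
  class(x) <- c("biomarker_table", class(x))
  x
}

#' Biomarker column names of a biomarker table
#' @param x A `biomarker_table`.
#' @return Character vector of biomarker column names.
#' @export
biomarker_names <- function(x) {
  setdiff(names(x), c("animal_id", "group"))
}

#' Process a long-format plate CSV into per-sample endpoints
#'
#' Takes raw plate data in the long layout (one row per read: well, sample,
#' role, replicate, time_s, absorbance, wavelength_nm, assay) and reduces a
#' single assay to per-sample values: kinetic slope per well where a time
#' course is present, then blank correction, then replicate aggregation.
#'
#' @param plate Data frame in the long plate layout.
#' @param assay Name of the assay to process.
#' @param kinetic Logical; `TRUE` for slope-based assays, `FALSE` for
#'   endpoint reads. Defaults to auto-detection from the presence of
#'   non-missing `time_s`.
#' @param cv_threshold Passed to [aggregate_replicates()].
#' @return A tibble of per-sample values (see [aggregate_replicates()]),
#'   with the blank value used stored in the `"blank_value"` attribute.
#' @export
process_plate <- function(plate, assay, kinetic = NULL, cv_threshold = 0.20) {
  plate <- tibble::as_tibble(plate)
  pl <- plate[plate$assay == assay, , drop = FALSE]
  if (!nrow(pl)) stop("no wells for assay '", assay, "'", call. = FALSE)
  if (is.null(kinetic)) kinetic <- any(!is.na(pl$time_s))
  if (kinetic) {
    per_well <- pl |>
      dplyr::group_by(.data$well, .data$sample, .data$role) |>
      dplyr::summarise(
        value = kinetic_rate(kinetic_trace(
          .data$well[1], .data$sample[1], .data$time_s, .data$absorbance,
          wavelength = .data$wavelength_nm[1], role = .data$role[1])),
        .groups = "drop"
      )
  } else {
    per_well <- pl |>
      dplyr::transmute(well = .data$well, sample = .data$sample,
                       role = .data$role, value = .data$absorbance)
  }
  bc <- blank_correct(stats::setNames(per_well$value, per_well$well),
                      per_well$role)
  keep <- per_well$role != "blank"
  out <- aggregate_replicates(bc$corrected, per_well$sample[keep],
                              cv_threshold = cv_threshold)
  attr(out, "blank_value") <- bc$blank_value
  out
}
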