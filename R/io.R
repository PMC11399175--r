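# CSV input/output for the package's exchange formats (tidy biomarker
# tables, long plate data, element-concentration tables) and the leachate
# summary operation.

#' Read a tidy biomarker table from CSV
#'
#' Expected layout: columns `animal_id`, `group`, then one numeric column
#' per biomarker; empty fields are missing values.
#'
#' @param path CSV file path.
#' @return A `biomarker_table`.
#' @export
read_biomarker_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  as_biomarker_table(x)
}

#' Write a biomarker table to CSV
#'
#' Comma-separated, UTF-8, `.` decimal separator, header row; missing
#' values as empty fields. An optional sidecar file records per-column
#' units and processing provenance.
#'
#' @param table A `biomarker_table`.
#' @param path Output CSV path.
#' @param sidecar Write `<path>.meta.yml` with unit metadata
#'   (default `TRUE` when units are attached).
#' @return `path`, invisibly.
#' @export
write_biomarker_table <- function(table, path,
                                  sidecar = !is.null(attr(table, "units"))) {
  readr::write_csv(tibble::as_tibble(table), path, na = "")
  if (isTRUE(sidecar)) {
    meta <- list(units = as.list(attr(table, "units")),
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 generator = "ibrtox")
    yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  }
  invisible(path)
}

#' Read long-format plate data from CSV
#'
#' Columns: `well`, `sample`, `role` (sample|blank), `replicate`,
#' `time_s` (empty for endpoint reads), `absorbance`, `wavelength_nm`,
#' `assay`.
#'
#' @param path CSV file path.
#' @return Tibble in the long plate layout.
#' @export
read_plate_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"),
                  col_types = readr::cols(
                    well = "c", sample = "c", role = "c", replicate = "i",
                    time_s = "d", absorbance = "d", wavelength_nm = "d",
                    assay = "c"))
}

#' Read an element-concentration table
#'
#' Columns: `element` (symbol), `mean_ug_per_l`, `sd_ug_per_l`. Rows are
#' the detected elements of a leachate characterisation.
#'
#' @param path CSV file path; the default is the packaged e-waste leachate
#'   characterisation fixture.
#' @return Tibble with unique element symbols and finite concentrations.
#' @export
read_element_table <- function(path = system.file("extdata",
                                                  "leachate_elements.csv",
                                                  package = "ibrtox")) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (anyDuplicated(x$element)) {
    stop("duplicate element symbol(s): ",
         paste(unique(x$element[duplicated(x$element)]), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(is.finite(x$mean_ug_per_l)), all(x$mean_ug_per_l >= 0),
            all(is.finite(x$sd_ug_per_l)), all(x$sd_ug_per_l >= 0))
  x
}

#' Summarise a leachate element table
#'
#' Counts the detected elements, ranks them by mean concentration
#' (descending, ties broken alphabetically) and renders the conventional
#' ascending-order string (`"Y < Au < ... < Ni"`).
#'
#' @param table Element tibble from [read_element_table()] (rows = detected
#'   elements).
#' @param tested_elements Optional character vector of all element symbols
#'   assayed (must contain every detected element); enables the
#'   tested/undetected bookkeeping.
#' @return List with `n_detected`, `n_tested` (`NA` if not supplied),
#'   `undetected` (symbols tested but absent from the table), `ranking`
#'   (tibble sorted by descending mean), `top` (character vector of
#'   symbols, most abundant first) and `ascending_string`.
#' @export
summarize_leachate <- function(table, tested_elements = NULL) {
  if (anyDuplicated(table$element)) {
    stop("duplicate element symbol(s) in table", call. = FALSE)
  }
  if (!is.null(tested_elements)) {
    extra <- setdiff(table$element, tested_elements)
    if (length(extra)) {
      stop("detected element(s) not in tested_elements: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  ranking <- table[order(-table$mean_ug_per_l, table$element), , drop = FALSE]
  list(
    n_detected = nrow(table),
    n_tested = if (is.null(tested_elements)) NA_integer_
               else length(unique(tested_elements)),
    undetected = if (is.null(tested_elements)) character(0)
                 else sort(setdiff(tested_elements, table$element)),
    ranking = tibble::as_tibble(ranking),
    top = ranking$element,
    ascending_string = paste(rev(ranking$element), collapse = " < ")
  )
}
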