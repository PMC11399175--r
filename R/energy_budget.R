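# Cellular energy allocation: Ea = protein + glucose + lipid energy
# reserves, Ec = energy consumption (electron-transport-system activity),
# CEA = Ea - Ec.

#' Energy available from reserves
#'
#' Sum of the three energy reserves measured in muscle tissue: protein,
#' glucose and lipid energy. Any missing component makes the budget
#' incomputable for that animal (`NA`, not an error).
#'
#' @param protein,glucose,lipid Numeric vectors of reserve energy in a
#'   common (possibly unitless, assay-normalised) energy-equivalent unit;
#'   negative values are rejected.
#' @return `protein + glucose + lipid`, `NA` where any component is missing.
#' @export
#' @examples
#' energy_available(30, 10, 20)  # 60
energy_available <- function(protein, glucose, lipid) {
  n <- max(length(protein), length(glucose), length(lipid))
  protein <- rep_len(protein, n); glucose <- rep_len(glucose, n)
  lipid <- rep_len(lipid, n)
  neg <- function(x) any(!is.na(x) & x < 0)
  if (neg(protein) || neg(glucose) || neg(lipid)) {
    stop("energy reserve components must be >= 0", call. = FALSE)
  }
  protein + glucose + lipid
}

#' Cellular energy allocation
#'
#' CEA = Ea - Ec: the net energy budget of the animal. Negative values are
#' meaningful (consumption exceeding reserves) and preserved.
#'
#' @param ea Energy available (see [energy_available()]).
#' @param ec Energy consumed.
#' @return `ea - ec`, `NA` where either is missing.
#' @export
cellular_energy_allocation <- function(ea, ec) {
  ea - ec
}

#' Append Ea and CEA columns to a biomarker table
#'
#' Reads the `protein_energy`, `glucose_energy`, `lipid_energy` and `Ec`
#' columns and appends `Ea` and `CEA`. Optional per-component conversion
#' factors rescale reserves before summing (all 1 by default, i.e. the
#' reserves are summed in the normalised assay units they arrive in).
#'
#' @param table A `biomarker_table` containing the four energy columns.
#' @param conversion Named numeric vector of factors for
#'   `protein_energy`, `glucose_energy`, `lipid_energy` (defaults all 1).
#' @return The table with `Ea` and `CEA` columns appended.
#' @export
add_energy_budget <- function(table,
                              conversion = c(protein_energy = 1,
                                             glucose_energy = 1,
                                             lipid_energy = 1)) {
  need <- c("protein_energy", "glucose_energy", "lipid_energy", "Ec")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("energy budget needs column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cf <- function(nm) if (nm %in% names(conversion)) conversion[[nm]] else 1
  ea <- energy_available(table$protein_energy * cf("protein_energy"),
                         table$glucose_energy * cf("glucose_energy"),
                         table$lipid_energy * cf("lipid_energy"))
  table$Ea <- ea
  table$CEA <- cellular_energy_allocation(ea, table$Ec)
  table
}
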