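# Oligomer-aware complex concentrations, pairwise molar ratios, cross-muscle
# percentage comparisons, and Stac3-DHPRalpha1s fractional occupancy.

.check_mode <- function(mode) {
  match.arg(mode, c("full_precision", "as_printed"))
}

# Round to `digits` decimals of the exact binary value (as decimal printing
# does): 0.86/4 is stored as 0.2149999..., so it prints - and must round - to
# 0.21, whereas base round() treats it as the decimal 0.215 and yields 0.22,
# contradicting tabulated values.
.round_printed <- function(x, digits) {
  out <- as.numeric(sprintf("%.*f", digits, x))
  out[is.na(x)] <- NA_real_
  out
}

#' Concentration of an oligomeric complex from its monomer concentration
#'
#' A homo-oligomer of `k` subunits assembles at `monomer_conc / k`; e.g. the
#' RyR1 calcium-release channel is a homotetramer (`k = 4`) and Orai1 a
#' hexamer (`k = 6`). In `"as_printed"` mode the result is rounded to 2
#' decimal places, matching how complex concentrations are conventionally
#' tabulated next to monomer values.
#'
#' @param monomer_conc Monomer concentration, µmol/kg wet weight (>= 0).
#' @param k Subunits per complex (integer >= 1).
#' @param mode `"full_precision"` (default) or `"as_printed"`.
#' @return Complex concentration, µmol/kg wet weight.
#' @export
complex_concentration <- function(monomer_conc, k = 1L,
                                  mode = "full_precision") {
  mode <- .check_mode(mode)
  if (any(k < 1)) stop("`k` must be >= 1")
  if (any(monomer_conc < 0, na.rm = TRUE))
    stop("`monomer_conc` must be >= 0")
  out <- monomer_conc / k
  if (mode == "as_printed") out <- .round_printed(out, 2L)
  out
}

#' Molar ratio of two protein (complex) concentrations
#'
#' In `"as_printed"` mode the inputs are first rounded to 2 decimal places
#' (the precision at which concentrations are tabulated) and the ratio is
#' reported to 3 significant digits — reproducing ratios computed from a
#' printed concentration table rather than from full-precision values.
#'
#' @param numer,denom Concentrations, µmol/kg wet weight (`denom > 0`).
#' @param mode `"full_precision"` (default) or `"as_printed"`.
#' @return Dimensionless ratio; `NA` inputs propagate.
#' @export
stoich_ratio <- function(numer, denom, mode = "full_precision") {
  mode <- .check_mode(mode)
  if (any(!is.na(denom) & denom <= 0))
    stop("`denom` must be > 0 (undefined ratio)")
  if (mode == "as_printed") {
    numer <- .round_printed(numer, 2L)
    denom <- .round_printed(denom, 2L)
    if (any(!is.na(denom) & denom <= 0))
      stop("`denom` rounds to 0 at printed precision (undefined ratio)")
    signif(numer / denom, 3L)
  } else {
    numer / denom
  }
}

#' Express a concentration as an integer percentage of a reference
#'
#' @param value,reference Concentrations in the same units (`reference > 0`).
#' @return `100 * value / reference`, rounded to the nearest integer percent.
#' @export
percent_of_reference <- function(value, reference) {
  if (any(reference <= 0)) stop("`reference` must be > 0")
  round(100 * value / reference)
}

#' Fractional occupancy of a 1:1 binding site
#'
#' Single-site Langmuir isotherm `C / (C + Kd)`, with the ligand
#' concentration converted from µmol/kg wet weight to µM via a tissue density
#' assumption (default 1 kg/L, under which µmol/kg equals µM).
#'
#' @param conc Free-ligand concentration, µmol/kg wet weight (>= 0).
#' @param kd Equilibrium dissociation constant, µM (> 0).
#' @param density_kg_per_l Tissue density converting µmol/kg to µM
#'   (default 1).
#' @return Occupied fraction in `[0, 1)`.
#' @export
fractional_occupancy <- function(conc, kd, density_kg_per_l = 1) {
  if (any(kd <= 0)) stop("`kd` must be > 0")
  if (any(conc < 0)) stop("`conc` must be >= 0")
  if (density_kg_per_l <= 0) stop("`density_kg_per_l` must be > 0")
  c_um <- conc * density_kg_per_l
  c_um / (c_um + kd)
}

#' Build a stoichiometry table of pairwise complex ratios
#'
#' One row per requested (numerator, denominator) pair and condition. Monomer
#' concentrations are divided by the oligomer subunit counts before the ratio
#' is formed. Pairs whose denominator (or numerator) protein is not detected
#' in a condition yield a `"-"` display entry and an `NA` ratio.
#'
#' @param concentrations Output of [protein_concentration()] (or any
#'   `data.frame` with `accession`, `condition`, `mean_umol_per_kg`,
#'   `detected`).
#' @param oligomers Named integer vector: accession -> subunits per complex
#'   (accessions not named default to 1).
#' @param pairs List of length-2 character vectors
#'   `c(numerator, denominator)`.
#' @param mode `"full_precision"` or `"as_printed"` (see [stoich_ratio()]).
#' @return `data.frame`: `numerator`, `denominator`, `condition`, `ratio`,
#'   `display`, `mode`.
#' @export
build_stoichiometry_report <- function(concentrations, oligomers = NULL,
                                       pairs, mode = "full_precision") {
  mode <- .check_mode(mode)
  if (is.null(oligomers)) oligomers <- integer(0)
  conds <- unique(concentrations$condition)
  get_complex <- function(acc, cond) {
    row <- concentrations[concentrations$accession == acc &
                            concentrations$condition == cond, , drop = FALSE]
    if (nrow(row) == 0L) return(NA_real_)
    if (!isTRUE(row$detected[1L])) return(NA_real_)
    k <- if (acc %in% names(oligomers)) oligomers[[acc]] else 1L
    complex_concentration(row$mean_umol_per_kg[1L], k, mode)
  }
  out <- list()
  for (pair in pairs) {
    for (cond in conds) {
      num <- get_complex(pair[1L], cond)
      den <- get_complex(pair[2L], cond)
      r <- if (is.na(num) || is.na(den) || den <= 0) NA_real_ else
        stoich_ratio(num, den, mode)
      out[[length(out) + 1L]] <- data.frame(
        numerator = pair[1L], denominator = pair[2L], condition = cond,
        ratio = r,
        display = if (is.na(r)) "-" else format(r, trim = TRUE),
        mode = mode, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
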