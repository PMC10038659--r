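# PRM/SID absolute quantification in µmol/kg wet weight, and the
# iBAQ <-> absolute-concentration calibration curve with linear-domain
# extrapolation.

#' Normalize PRM light/heavy ratios by sample TIC
#'
#' Corrects for injected-amount variation: each sample's light/heavy ratios
#' are scaled by `reference TIC / sample TIC`, with the reference being the
#' mean TIC across samples. The scaling is applied to `light_area` so the
#' table schema is preserved.
#'
#' @param table PRM `data.frame` with `sample_id`, `light_area`, `heavy_area`,
#'   `sample_tic`.
#' @return List with the normalized `table` and the per-sample `factors`.
#' @export
tic_normalize <- function(table) {
  tic <- tapply(table$sample_tic, table$sample_id, function(x) x[1L])
  if (any(tic <= 0)) stop("sample(s) with non-positive TIC")
  factors <- stats::setNames(as.vector(mean(tic) / tic), names(tic))
  table$light_area <- table$light_area * unname(factors[table$sample_id])
  list(table = table, factors = factors)
}

#' Convert a light/heavy area ratio to fmol analyte per µg total peptide
#'
#' With a heavy-reference spike of `spike_S` fmol per µg of total endogenous
#' peptide, the analyte amount is `(light_area / heavy_area) * spike_S`.
#' A zero light area yields 0 (below detection); a non-positive heavy area is
#' a quantification failure and raises an error.
#'
#' @param light_area,heavy_area Peak areas (vectors recycle).
#' @param spike_S Spike amount, fmol heavy peptide per µg peptide (default 10).
#' @return fmol analyte per µg total peptide.
#' @export
peptide_fmol_per_ug <- function(light_area, heavy_area, spike_S = 10) {
  if (spike_S <= 0) stop("`spike_S` must be > 0")
  if (any(heavy_area <= 0))
    stop("non-positive heavy area: peptide cannot be quantified")
  (light_area / heavy_area) * spike_S
}

#' Protein concentrations in µmol/kg wet weight from a PRM table
#'
#' Per sample, the peptide-level fmol/µg values of a protein are summarized by
#' the median on the log scale and back-transformed (equal to the linear-scale
#' median for an odd peptide count); the concentration is
#' `fmol/µg * yield_Y * 1e-3` µmol/kg. Mean and SD are then taken across the
#' samples of each condition. Rows with non-positive heavy areas are flagged
#' non-quantifiable; a protein with no quantifiable peptide in any sample of a
#' condition is reported "not detected" (`detected = FALSE`, `NA` mean), as is
#' a protein whose measured concentration is zero (below detection).
#'
#' @param table PRM `data.frame` (TIC-normalized light areas; see
#'   [tic_normalize()]). A `condition` column groups samples; absent, all
#'   samples form one condition `"all"`.
#' @param spike_S fmol heavy peptide per µg peptide (default 10).
#' @param yield_Y µg peptide per mg wet tissue (default 64.5).
#' @return `data.frame`: `accession`, `condition`, `mean_umol_per_kg`,
#'   `sd_umol_per_kg`, `n_samples`, `detected`, `n_flagged` (non-quantifiable
#'   peptide measurements).
#' @export
protein_concentration <- function(table, spike_S = 10, yield_Y = 64.5) {
  if (spike_S <= 0) stop("`spike_S` must be > 0")
  if (yield_Y <= 0) stop("`yield_Y` must be > 0")
  if (!"condition" %in% names(table)) table$condition <- "all"
  ok <- table$heavy_area > 0
  groups <- split(seq_len(nrow(table)),
                  list(accession = table$accession,
                       condition = table$condition), drop = TRUE)
  rows <- lapply(groups, function(idx) {
    sub <- table[idx, , drop = FALSE]
    quant <- sub[sub$heavy_area > 0, , drop = FALSE]
    n_flagged <- nrow(sub) - nrow(quant)
    acc <- sub$accession[1L]
    cond <- sub$condition[1L]
    n_total_samples <- length(unique(sub$sample_id))
    if (nrow(quant) == 0L) {
      return(data.frame(accession = acc, condition = cond,
                        mean_umol_per_kg = NA_real_, sd_umol_per_kg = NA_real_,
                        n_samples = n_total_samples, detected = FALSE,
                        n_flagged = n_flagged, stringsAsFactors = FALSE))
    }
    fmol <- peptide_fmol_per_ug(quant$light_area, quant$heavy_area, spike_S)
    per_sample <- tapply(fmol, quant$sample_id, function(x)
      exp(stats::median(log(x))))
    conc <- per_sample * yield_Y * 1e-3
    m <- mean(conc)
    data.frame(accession = acc, condition = cond,
               mean_umol_per_kg = if (m > 0) m else NA_real_,
               sd_umol_per_kg = if (m > 0 && length(conc) > 1L)
                 stats::sd(conc) else if (m > 0) 0 else NA_real_,
               n_samples = length(conc), detected = m > 0,
               n_flagged = n_flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the iBAQ-to-absolute calibration curve
#'
#' Ordinary least squares of log2 absolute concentration (µmol/kg) on log2
#' iBAQ for the anchor proteins quantified by PRM/SID. The fitted linear
#' domain is the x-range of the anchors.
#'
#' @param log2_ibaq,log2_conc Anchor coordinates (>= 2 anchors, distinct x).
#' @return A `"calibration_model"`: `slope`, `intercept`, `r_squared`,
#'   `domain`, and the underlying `stats::lm` fit.
#' @export
fit_calibration <- function(log2_ibaq, log2_conc) {
  if (length(log2_ibaq) != length(log2_conc) || length(log2_ibaq) < 2L)
    stop("need >= 2 anchors")
  if (length(unique(log2_ibaq)) < 2L)
    stop("anchor x-values are degenerate (zero spread)")
  fit <- stats::lm(log2_conc ~ log2_ibaq)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log2_conc - mean(log2_conc))^2)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    domain = range(log2_ibaq),
    fit = fit
  ), class = "calibration_model")
}

#' Extrapolate absolute concentrations from the calibration curve
#'
#' Returns `2^(slope * x + intercept)` in µmol/kg for each log2-iBAQ value.
#' Values outside the fitted linear domain are still computed but flagged
#' `out_of_domain`.
#'
#' @param model A fitted [fit_calibration()] model.
#' @param log2_ibaq Query log2-iBAQ values.
#' @return `data.frame`: `log2_ibaq`, `umol_per_kg`, `out_of_domain`.
#' @export
extrapolate <- function(model, log2_ibaq) {
  if (!inherits(model, "calibration_model"))
    stop("`model` must be a fitted calibration model")
  y <- 2^(model$slope * log2_ibaq + model$intercept)
  data.frame(
    log2_ibaq = log2_ibaq,
    umol_per_kg = y,
    out_of_domain = log2_ibaq < model$domain[1L] |
      log2_ibaq > model$domain[2L]
  )
}
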