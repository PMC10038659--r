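# Reporter-ion relative quantification: isotope-impurity correction, global
# channel normalization, protein roll-up with iBAQ, empirical-Bayes moderated
# t-statistics and BH FDR, and the study's significance filter.

# Resolve the reporter-intensity columns of a PSM/protein table.
.channel_cols <- function(table, channels = NULL) {
  ch <- channels %||% attr(table, "channels") %||%
    intersect(tmt10_channels(), names(table))
  if (!length(ch) || !all(ch %in% names(table)))
    stop("cannot resolve reporter channel columns")
  ch
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correct reporter intensities for isotope-impurity cross-leakage
#'
#' Each row's observed intensity vector is replaced by the solution of
#' `impurity %*% corrected = observed`; negative solutions are clipped to 0
#' and counted (`attr(,"n_clipped")`, with a warning).
#'
#' @param table PSM `data.frame` with reporter-intensity columns.
#' @param impurity Square cross-leakage matrix (channels x channels); the
#'   identity matrix leaves the table unchanged.
#' @param channels Optional channel column names.
#' @return The corrected PSM table.
#' @export
correct_reporters <- function(table, impurity, channels = NULL) {
  ch <- .channel_cols(table, channels)
  if (!is.matrix(impurity) || nrow(impurity) != length(ch) ||
      ncol(impurity) != length(ch))
    stop("`impurity` must be a ", length(ch), "x", length(ch), " matrix")
  if (abs(det(impurity)) < .Machine$double.eps * 1e3)
    stop("impurity matrix is numerically singular")
  M <- as.matrix(table[, ch, drop = FALSE])
  corrected <- t(solve(impurity, t(M)))
  n_clipped <- sum(corrected < 0)
  if (n_clipped > 0) {
    warning(sprintf("%d corrected intensities were negative and clipped to 0",
                    n_clipped))
    corrected[corrected < 0] <- 0
  }
  table[, ch] <- corrected
  attr(table, "n_clipped") <- n_clipped
  table
}

#' Equalize total reporter intensity across channels
#'
#' Scales each channel so that all channel totals equal the mean
#' pre-normalization total; the grand total intensity is conserved.
#'
#' @param table PSM `data.frame`.
#' @param channels Optional channel column names.
#' @return List with the normalized `table` and the per-channel `factors`.
#' @export
normalize_channels <- function(table, channels = NULL) {
  ch <- .channel_cols(table, channels)
  M <- as.matrix(table[, ch, drop = FALSE])
  totals <- colSums(M)
  if (any(totals <= 0))
    stop("channel(s) with non-positive total intensity: ",
         paste(ch[totals <= 0], collapse = ", "))
  factors <- mean(totals) / totals
  table[, ch] <- sweep(M, 2L, factors, `*`)
  list(table = table, factors = stats::setNames(factors, ch))
}

#' Roll up PSM intensities to proteins
#'
#' Sums reporter intensities per protein and channel, counts distinct peptide
#' sequences, and computes the iBAQ index (total summed intensity divided by
#' the number of theoretically observable tryptic peptides).
#'
#' @param table PSM `data.frame` (calibration-mix rows are excluded unless
#'   `include_calibration = TRUE`).
#' @param db Protein database covering every PSM accession.
#' @param channels Optional channel column names.
#' @param include_calibration Keep calibration-mix rows?
#' @return Protein `data.frame`: `accession`, `n_peptides`,
#'   `n_observable_peptides`, `ibaq`, one intensity column per channel.
#' @export
rollup_proteins <- function(table, db, channels = NULL,
                            include_calibration = FALSE) {
  ch <- .channel_cols(table, channels)
  if (!include_calibration && "is_calibration" %in% names(table))
    table <- table[!table$is_calibration, , drop = FALSE]
  if (!all(table$accession %in% db$accession))
    stop("PSM accession(s) missing from the protein database: ",
         paste(unique(setdiff(table$accession, db$accession)), collapse = ", "))
  M <- rowsum(as.matrix(table[, ch, drop = FALSE]), table$accession)
  acc <- rownames(M)
  n_pep <- vapply(split(table$peptide, table$accession),
                  function(p) length(unique(p)), integer(1))[acc]
  seqs <- stats::setNames(db$sequence, db$accession)
  n_obs <- vapply(acc, function(a) count_observable_peptides(seqs[[a]]),
                  integer(1))
  ibaq <- ifelse(n_obs > 0, rowSums(M) / n_obs, NA_real_)
  out <- cbind(
    data.frame(accession = acc, n_peptides = unname(n_pep),
               n_observable_peptides = unname(n_obs), ibaq = unname(ibaq),
               stringsAsFactors = FALSE),
    as.data.frame(M, check.names = FALSE)
  )
  rownames(out) <- NULL
  attr(out, "channels") <- ch
  out
}

#' Channel design for a two-condition comparison
#'
#' @param labels Named character vector: channel -> condition label.
#' @param condition1 Reference condition (denominator of the ratio).
#' @param condition2 Contrast condition (numerator).
#' @return Classed list (`"channel_design"`).
#' @export
channel_design <- function(labels, condition1 = "WT", condition2 = "dHT") {
  if (is.null(names(labels))) stop("`labels` must be named by channel")
  if (!all(c(condition1, condition2) %in% labels))
    stop("both conditions must be present in `labels`")
  structure(list(labels = labels, channels = names(labels),
                 condition1 = condition1, condition2 = condition2),
            class = "channel_design")
}

# Newton solve of trigamma(y) = x (x > 0), for the moment-matching estimator.
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Estimate variance-moderation hyperparameters
#'
#' Moment matching on the log sample variances: with
#' `e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)`, the prior degrees of
#' freedom `d0` solve `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` and
#' the prior variance is recovered from `mean(e)`. When the observed spread
#' of log-variances is no larger than expected from sampling alone, `d0` is
#' infinite and `s0_sq` is the (geometric-mean-based) common variance.
#'
#' @param s2 Per-protein pooled sample variances (> 0).
#' @param df Their residual degrees of freedom.
#' @return List with `d0` (prior df, possibly `Inf`) and `s0_sq` (prior
#'   variance).
#' @export
estimate_moderation <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0 & df > 0
  # degenerate ensembles (e.g. exact replicates): a common-variance prior
  if (sum(ok) < 2L)
    return(list(d0 = Inf, s0_sq = mean(s2[is.finite(s2)])))
  z <- log(s2[ok])
  dg <- df[ok]
  e <- z - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(dg / 2))
  if (!is.finite(evar) || evar <= 0)
    return(list(d0 = Inf, s0_sq = exp(emean)))
  d0 <- 2 * .trigamma_inverse(evar)
  s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated t-test on protein channel intensities
#'
#' On log2 intensities, per protein: the condition-mean difference, the pooled
#' within-condition variance `s2_g` with `d_g = n1 + n2 - 2` df, the posterior
#' variance `(d0*s0_sq + d_g*s2_g) / (d0 + d_g)` under the estimated (or
#' supplied) prior, the moderated t statistic and a two-sided p-value on
#' `d0 + d_g` df. `hyperparams = list(d0 = 0)` reduces to the ordinary pooled
#' t-test; `d0 = Inf` tests every protein against the common prior variance.
#'
#' Proteins with any non-positive channel intensity are excluded (the log is
#' undefined); their number is stored in `attr(,"n_excluded")`.
#'
#' @param quants Protein table from [rollup_proteins()].
#' @param design A [channel_design()]; each condition needs >= 2 channels.
#' @param hyperparams Optional `list(d0=, s0_sq=)` overriding estimation.
#' @return `data.frame`: `accession`, `ratio` (condition2/condition1),
#'   `log2fc`, `t_moderated`, `df_total`, `p_value`, `n_peptides`; the fitted
#'   prior is in `attr(,"hyperparams")`.
#' @export
moderated_t <- function(quants, design, hyperparams = NULL) {
  stopifnot(inherits(design, "channel_design"))
  ch <- design$channels
  if (!all(ch %in% names(quants))) stop("design channels missing from `quants`")
  i1 <- ch[design$labels == design$condition1]
  i2 <- ch[design$labels == design$condition2]
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("each condition needs >= 2 channels")
  M <- as.matrix(quants[, ch, drop = FALSE])
  ok <- apply(M > 0, 1L, all)
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    message(n_excluded,
            " protein(s) with non-positive intensities excluded from testing")
  q <- quants[ok, , drop = FALSE]
  L <- log2(as.matrix(q[, ch, drop = FALSE]))
  m1 <- rowMeans(L[, i1, drop = FALSE])
  m2 <- rowMeans(L[, i2, drop = FALSE])
  delta <- m2 - m1
  ss1 <- rowSums((L[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((L[, i2, drop = FALSE] - m2)^2)
  dg <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / dg
  hyper <- hyperparams %||% estimate_moderation(s2, rep(dg, length(s2)))
  d0 <- hyper$d0
  if (d0 == 0) {
    s2_post <- s2
    df_total <- rep(dg, length(s2))
  } else if (is.infinite(d0)) {
    s2_post <- rep(hyper$s0_sq, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    s2_post <- (d0 * hyper$s0_sq + dg * s2) / (d0 + dg)
    df_total <- rep(d0 + dg, length(s2))
  }
  denom <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- delta / denom
  tstat[delta == 0 & denom == 0] <- 0  # exact replicates, no difference
  p <- 2 * stats::pt(-abs(tstat), df_total)
  out <- data.frame(
    accession = q$accession, ratio = 2^delta, log2fc = delta,
    t_moderated = tstat, df_total = df_total, p_value = p,
    n_peptides = q$n_peptides, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "hyperparams") <- hyper
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values), monotone-consistent with the BH
#' procedure and capped at 1.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Full differential-abundance stage: moderated t + BH + significance flag
#'
#' @inheritParams moderated_t
#' @inheritParams filter_significant
#' @return [moderated_t()] output plus `q_value` and `significant` columns.
#' @export
differential_abundance <- function(quants, design, q_max = 0.05,
                                   fold_min = 0.2, min_peptides = 2L,
                                   hyperparams = NULL) {
  res <- moderated_t(quants, design, hyperparams = hyperparams)
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$q_value < q_max &
    abs(res$ratio - 1) >= fold_min &
    res$n_peptides >= min_peptides
  res
}

#' Apply the study's significance filter
#'
#' Keeps proteins with `q_value < q_max`, an abundance change of at least
#' `fold_min` (i.e. `|ratio - 1| >= fold_min`, so ratio <= 0.80 or >= 1.20 at
#' the default), and more than one supporting peptide; reports up/down counts.
#'
#' @param results Differential results with `ratio`, `q_value` (computed from
#'   `p_value` if absent) and `n_peptides`.
#' @param q_max FDR threshold (default 0.05).
#' @param fold_min Minimum absolute deviation of the ratio from 1
#'   (default 0.2).
#' @param min_peptides Minimum distinct peptides (default 2).
#' @return List: filtered `table`, `n_up` (ratio > 1), `n_down` (ratio < 1).
#' @export
filter_significant <- function(results, q_max = 0.05, fold_min = 0.2,
                               min_peptides = 2L) {
  if (!"q_value" %in% names(results))
    results$q_value <- bh_adjust(results$p_value)
  keep <- results$q_value < q_max &
    abs(results$ratio - 1) >= fold_min &
    results$n_peptides >= min_peptides
  kept <- results[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(table = kept,
       n_up = sum(kept$ratio > 1),
       n_down = sum(kept$ratio < 1))
}
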