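# Seeded generators for synthetic study inputs: a protein database, TMT 10-plex
# PSM tables and PRM/SID tables with known ground truth, so every downstream
# stage can be exercised and validated without any raw mass-spectrometry data.

#' The 20 canonical amino-acid one-letter codes
#' @return Character vector of length 20.
#' @export
canonical_residues <- function() {
  c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# Rough vertebrate-proteome residue frequencies; K and R kept at their natural
# ~5-6% so tryptic cleavage sites occur at realistic density (~1 per 9 residues).
.aa_freq <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025, E = 0.063,
  Q = 0.058, G = 0.074, H = 0.026, I = 0.068, L = 0.099, K = 0.058,
  M = 0.025, F = 0.047, P = 0.039, S = 0.057, T = 0.051, W = 0.013,
  Y = 0.032, V = 0.073
)

#' TMT 10-plex reporter channel names
#' @return Character vector of the ten reporter-channel labels.
#' @export
tmt10_channels <- function() {
  c("126", "127N", "127C", "128N", "128C", "129N", "129C", "130N", "130C", "131")
}

#' Generate a synthetic protein sequence database
#'
#' Sequences are drawn residue-by-residue from realistic amino-acid
#' frequencies, so tryptic cleavage sites (K/R not before P) occur at their
#' natural density. Deterministic for a fixed seed.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param mean_length Mean sequence length in residues (>= 10); individual
#'   lengths are Poisson-distributed around this value (floored at 10).
#' @param seed Integer RNG seed.
#' @param accession_prefix Prefix for the generated accessions.
#' @return A `data.frame` with columns `accession`, `description`, `sequence`.
#' @export
generate_protein_db <- function(n_proteins, mean_length = 300, seed = 1L,
                                accession_prefix = "SYNP") {
  if (!is.numeric(n_proteins) || length(n_proteins) != 1L || n_proteins < 1)
    stop("`n_proteins` must be a single number >= 1")
  if (!is.numeric(mean_length) || length(mean_length) != 1L || mean_length < 10)
    stop("`mean_length` must be a single number >= 10")
  n_proteins <- as.integer(n_proteins)
  set.seed(as.integer(seed))
  lens <- pmax(10L, stats::rpois(n_proteins, mean_length))
  seqs <- vapply(lens, function(L) {
    paste(sample(names(.aa_freq), L, replace = TRUE, prob = .aa_freq),
          collapse = "")
  }, character(1))
  data.frame(
    accession = sprintf("%s%05d", accession_prefix, seq_len(n_proteins)),
    description = sprintf("synthetic protein %d", seq_len(n_proteins)),
    sequence = seqs,
    stringsAsFactors = FALSE
  )
}

#' In-silico tryptic digestion
#'
#' Cleaves after lysine or arginine unless the next residue is proline, and
#' enumerates all peptides with up to `missed_cleavages` internal uncleaved
#' sites.
#'
#' @param sequence A single non-empty amino-acid string.
#' @param missed_cleavages Maximum number of missed cleavages (>= 0).
#' @return Character vector of peptides in positional order (repeated
#'   fragments are kept, so the 0-missed-cleavage result concatenates back to
#'   the input sequence).
#' @export
digest_tryptic <- function(sequence, missed_cleavages = 0L) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("`sequence` must be a single non-empty string")
  if (!is.numeric(missed_cleavages) || length(missed_cleavages) != 1L ||
      missed_cleavages < 0)
    stop("`missed_cleavages` must be a single number >= 0")
  missed_cleavages <- as.integer(missed_cleavages)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)
  frags <- substring(sequence, utils::head(bounds, -1L) + 1L,
                     utils::tail(bounds, -1L))
  k <- length(frags)
  out <- character(0)
  for (mc in 0:missed_cleavages) {
    if (mc + 1L > k) break
    starts <- seq_len(k - mc)
    out <- c(out, vapply(starts, function(i)
      paste(frags[i:(i + mc)], collapse = ""), character(1)))
  }
  out
}

#' Count theoretically observable tryptic peptides (iBAQ denominator)
#'
#' Counts the distinct fully tryptic, zero-missed-cleavage peptides whose
#' length falls in `[min_length, max_length]` — the standard iBAQ convention.
#'
#' @param sequence Amino-acid string.
#' @param min_length,max_length Inclusive peptide-length window (default 7-30).
#' @return Integer count.
#' @export
count_observable_peptides <- function(sequence, min_length = 7L, max_length = 30L) {
  peps <- unique(digest_tryptic(sequence, 0L))
  sum(nchar(peps) >= min_length & nchar(peps) <= max_length)
}

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generator: the channel ->
#' condition design, noise magnitudes, the heavy-peptide spike amount and the
#' tissue peptide yield that links fmol/µg to µmol/kg wet weight.
#'
#' @param design Named character vector mapping each reporter channel to a
#'   condition label; default: TMT 10-plex with channels 1-5 = `"WT"` and
#'   channels 6-10 = `"dHT"`.
#' @param condition1,condition2 Reference and contrast condition labels.
#' @param peptide_ionization_sigma Log-scale SD of peptide ionization
#'   efficiencies (log-normal, fixed per peptide across channels).
#' @param reporter_noise_cv Multiplicative CV of reporter-ion noise.
#' @param channel_loading Per-channel multiplicative loading factors
#'   (default all 1).
#' @param spike_fmol_per_ug Heavy reference peptide spike, fmol per µg of total
#'   endogenous peptide (default 10).
#' @param yield_ug_per_mg Peptide yield, µg peptide per mg wet tissue
#'   (default 64.5).
#' @param prm_cv Multiplicative CV of PRM peptide-level ratio noise.
#' @param tic_drift_cv CV of per-sample total-ion-chromatogram drift.
#' @param missingness_rate Fraction of PSM rows dropped at random, in `[0, 1)`.
#' @param n_samples PRM samples per condition (default 5).
#' @param intensity_scale Reporter counts per µmol/kg of protein (arbitrary
#'   instrument scale, default 1e6).
#' @param tic_base Baseline TIC value (default 5e9).
#' @param heavy_area_base Baseline heavy-peptide peak area (default 1e5).
#' @param seed Integer RNG seed.
#' @return A classed list (`"sim_config"`).
#' @export
sim_config <- function(design = NULL,
                       condition1 = "WT", condition2 = "dHT",
                       peptide_ionization_sigma = 1.0,
                       reporter_noise_cv = 0.10,
                       channel_loading = NULL,
                       spike_fmol_per_ug = 10,
                       yield_ug_per_mg = 64.5,
                       prm_cv = 0.10,
                       tic_drift_cv = 0.05,
                       missingness_rate = 0,
                       n_samples = 5L,
                       intensity_scale = 1e6,
                       tic_base = 5e9,
                       heavy_area_base = 1e5,
                       seed = 1L) {
  if (is.null(design)) {
    design <- stats::setNames(rep(c(condition1, condition2), each = 5L),
                              tmt10_channels())
  }
  if (is.null(names(design)) || anyDuplicated(names(design)))
    stop("`design` must be a named vector with unique channel names")
  if (!all(c(condition1, condition2) %in% design))
    stop("both `condition1` and `condition2` must appear in `design`")
  if (is.null(channel_loading))
    channel_loading <- stats::setNames(rep(1, length(design)), names(design))
  if (length(channel_loading) != length(design))
    stop("`channel_loading` must have one factor per channel")
  if (is.null(names(channel_loading)))
    names(channel_loading) <- names(design)
  cvs <- c(peptide_ionization_sigma, reporter_noise_cv, prm_cv, tic_drift_cv)
  if (any(cvs < 0)) stop("noise parameters must be >= 0")
  if (spike_fmol_per_ug <= 0) stop("`spike_fmol_per_ug` must be > 0")
  if (yield_ug_per_mg <= 0) stop("`yield_ug_per_mg` must be > 0")
  if (missingness_rate < 0 || missingness_rate >= 1)
    stop("`missingness_rate` must be in [0, 1)")
  if (n_samples < 1) stop("`n_samples` must be >= 1")
  structure(list(
    design = design, channels = names(design),
    condition1 = condition1, condition2 = condition2,
    peptide_ionization_sigma = peptide_ionization_sigma,
    reporter_noise_cv = reporter_noise_cv,
    channel_loading = channel_loading,
    spike_fmol_per_ug = spike_fmol_per_ug,
    yield_ug_per_mg = yield_ug_per_mg,
    prm_cv = prm_cv, tic_drift_cv = tic_drift_cv,
    missingness_rate = missingness_rate,
    n_samples = as.integer(n_samples),
    intensity_scale = intensity_scale,
    tic_base = tic_base, heavy_area_base = heavy_area_base,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Ground truth for a simulated study
#'
#' @param concentration Named numeric vector: accession -> µmol/kg wet weight
#'   in the reference condition (all >= 0).
#' @param fold_change Named numeric vector: accession -> condition2/condition1
#'   abundance ratio (> 0; proteins not named default to 1).
#' @param calibration_mix Optional numeric matrix of known per-channel amounts
#'   (rows = calibration-mix accessions, columns = channels); calibration
#'   proteins must be disjoint from the study proteins.
#' @return A classed list (`"ground_truth"`).
#' @export
ground_truth <- function(concentration, fold_change = NULL,
                         calibration_mix = NULL) {
  if (is.null(names(concentration)) || any(!nzchar(names(concentration))))
    stop("`concentration` must be a named vector")
  if (any(concentration < 0)) stop("concentrations must be >= 0")
  if (is.null(fold_change)) fold_change <- numeric(0)
  if (length(fold_change) && (is.null(names(fold_change)) ||
                              any(fold_change <= 0)))
    stop("`fold_change` must be a named vector of positive ratios")
  if (!is.null(calibration_mix)) {
    if (is.null(rownames(calibration_mix)))
      stop("`calibration_mix` needs accession rownames")
    if (any(rownames(calibration_mix) %in% names(concentration)))
      stop("calibration-mix proteins must be disjoint from study proteins")
    if (any(calibration_mix < 0)) stop("calibration amounts must be >= 0")
  }
  structure(list(concentration = concentration, fold_change = fold_change,
                 calibration_mix = calibration_mix),
            class = "ground_truth")
}

#' Default six-protein calibration mix amounts
#'
#' Six calibration proteins mixed in a geometric series across channels
#' (each channel differs from the previous by `step`), emulating a digested
#' standard-protein mixture added before labeling to monitor ratio distortion.
#'
#' @param channels Channel names (default TMT 10-plex).
#' @param base Amount in the first channel (arbitrary intensity units).
#' @param step Geometric step between consecutive channels.
#' @return Matrix (6 proteins x channels) of known amounts.
#' @export
calibration_mix_amounts <- function(channels = tmt10_channels(),
                                    base = 1000, step = 1.5) {
  acc <- sprintf("CALIB%02d", 1:6)
  amounts <- outer(base * 2^(0:5), step^(seq_along(channels) - 1L))
  dimnames(amounts) <- list(acc, channels)
  amounts
}

# Median-one (log-symmetric) multiplicative log-normal noise with the given
# linear-scale CV. Median 1 pairs naturally with the median-based PRM
# summary; condition differences of log-intensity means are unaffected by
# the choice of meanlog.
.mult_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = 0, sdlog = sqrt(log1p(cv^2)))
}

# Symmetric (Gaussian) multiplicative noise, mean 1, SD = cv, clamped
# positive. Used for PRM peak-area and TIC-drift noise, where the symmetric
# form keeps the median-based protein summary mean-unbiased.
.mult_noise_gauss <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  pmax(stats::rnorm(n, mean = 1, sd = cv), 1e-6)
}

#' Enumerate the tryptic peptides backing simulated PSMs
#'
#' One row per (protein, peptide): zero-missed-cleavage tryptic peptides of
#' length 6-30 (falling back to the longest fragment for proteins with none),
#' the peptide population the simulator turns into PSM rows.
#'
#' @param db Protein database `data.frame` (`accession`, `sequence`).
#' @param min_length,max_length Peptide length window.
#' @return `data.frame` with columns `accession`, `peptide`.
#' @export
tryptic_peptide_table <- function(db, min_length = 6L, max_length = 30L) {
  pep_list <- lapply(seq_len(nrow(db)), function(i) {
    p <- unique(digest_tryptic(db$sequence[i], 0L))
    keep <- p[nchar(p) >= min_length & nchar(p) <= max_length]
    if (!length(keep)) keep <- p[which.max(nchar(p))]
    keep
  })
  data.frame(
    accession = rep(db$accession, lengths(pep_list)),
    peptide = unlist(pep_list, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Simulate a TMT 10-plex PSM table
#'
#' Intensity model per PSM row p and channel c:
#' `I(p,c) = A(protein, condition(c)) * e_p * l_c * eps`, where `A` is the
#' ground-truth abundance (condition2 channels multiplied by the protein's
#' fold change), `e_p` a log-normal peptide ionization efficiency fixed per
#' peptide, `l_c` the channel loading factor and `eps` mean-one multiplicative
#' reporter noise. Calibration-mix rows use the known per-channel amounts in
#' place of `A`. Rows are dropped independently at `missingness_rate`.
#' Deterministic for a fixed `cfg$seed`.
#'
#' @param db Protein database containing every ground-truth accession.
#' @param truth A [ground_truth()] object.
#' @param cfg A [sim_config()] object.
#' @param peptides Optional precomputed [tryptic_peptide_table()] (saves
#'   re-digestion across replicate simulations).
#' @return PSM `data.frame`: `accession`, `peptide`, `is_calibration`, one
#'   intensity column per channel; channel names in `attr(,"channels")`.
#' @export
simulate_tmt <- function(db, truth, cfg = sim_config(), peptides = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))
  study_acc <- names(truth$concentration)
  calib_acc <- rownames(truth$calibration_mix)
  if (!all(study_acc %in% db$accession))
    stop("ground-truth accession(s) missing from the protein database: ",
         paste(setdiff(study_acc, db$accession), collapse = ", "))
  if (!is.null(calib_acc) && !all(calib_acc %in% db$accession))
    stop("calibration-mix accession(s) missing from the protein database")
  set.seed(cfg$seed)
  if (is.null(peptides)) {
    peptides <- tryptic_peptide_table(
      db[db$accession %in% c(study_acc, calib_acc), , drop = FALSE])
  }
  nch <- length(cfg$channels)

  study <- peptides[peptides$accession %in% study_acc, , drop = FALSE]
  fold <- rep(1, nrow(study))
  hit <- study$accession %in% names(truth$fold_change)
  fold[hit] <- truth$fold_change[study$accession[hit]]
  base <- truth$concentration[study$accession] * cfg$intensity_scale
  is_c2 <- cfg$design == cfg$condition2
  # abundance per row x channel
  A <- outer(base, rep(1, nch))
  A[, is_c2] <- A[, is_c2] * fold

  rows <- study
  if (!is.null(calib_acc)) {
    cal <- peptides[peptides$accession %in% calib_acc, , drop = FALSE]
    A <- rbind(A, truth$calibration_mix[cal$accession, cfg$channels,
                                        drop = FALSE])
    rows <- rbind(study, cal)
  }
  n <- nrow(rows)
  e_p <- .mult_noise(n, 0)
  sig <- cfg$peptide_ionization_sigma
  if (sig > 0) e_p <- stats::rlnorm(n, meanlog = -sig^2 / 2, sdlog = sig)
  eps <- matrix(.mult_noise(n * nch, cfg$reporter_noise_cv), n, nch)
  intens <- A * e_p * eps
  intens <- sweep(intens, 2L, cfg$channel_loading[cfg$channels], `*`)
  colnames(intens) <- cfg$channels

  out <- cbind(
    data.frame(accession = rows$accession, peptide = rows$peptide,
               is_calibration = rows$accession %in% calib_acc,
               stringsAsFactors = FALSE),
    as.data.frame(intens, check.names = FALSE)
  )
  if (cfg$missingness_rate > 0) {
    keep <- stats::runif(n) >= cfg$missingness_rate
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "channels") <- cfg$channels
  out
}

#' Simulate a PRM/SID table
#'
#' For each target peptide, sample and condition, the light/heavy peak-area
#' ratio has expectation `C / (S * Y * 1e-3)` — the inverse of the
#' concentration chain `fmol/µg x Y (µg/mg) x 1e-3 = µmol/kg` — perturbed by
#' mean-one multiplicative noise with CV `prm_cv`. Per-sample injection drift
#' (CV `tic_drift_cv`) multiplies the light area and the recorded sample TIC
#' alike, so TIC normalization can invert it. Deterministic for a fixed seed.
#'
#' @param db Protein database.
#' @param truth Either a [ground_truth()] object (its `concentration` is used
#'   as a single condition) or a `data.frame` with columns `accession`,
#'   `condition`, `umol_per_kg`.
#' @param target_peptides Named list: accession -> character vector of target
#'   peptides; each must be a valid tryptic peptide (<= 3 missed cleavages) of
#'   its protein.
#' @param cfg A [sim_config()] object.
#' @return PRM `data.frame`: `sample_id`, `condition`, `accession`, `peptide`,
#'   `light_area`, `heavy_area`, `sample_tic`.
#' @export
simulate_prm <- function(db, truth, target_peptides, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (inherits(truth, "ground_truth")) {
    conc <- data.frame(accession = names(truth$concentration),
                       condition = cfg$condition1,
                       umol_per_kg = unname(truth$concentration),
                       stringsAsFactors = FALSE)
  } else {
    conc <- as.data.frame(truth)
    stopifnot(all(c("accession", "condition", "umol_per_kg") %in% names(conc)))
  }
  acc <- unique(conc$accession)
  if (!all(acc %in% db$accession))
    stop("concentration accession(s) missing from the protein database")
  if (!all(acc %in% names(target_peptides)))
    stop("no target peptides for: ",
         paste(setdiff(acc, names(target_peptides)), collapse = ", "))
  seqs <- stats::setNames(db$sequence, db$accession)
  for (a in acc) {
    valid <- digest_tryptic(seqs[[a]], 3L)
    bad <- setdiff(target_peptides[[a]], valid)
    if (length(bad))
      stop("peptide(s) not in the tryptic digest of ", a, ": ",
           paste(bad, collapse = ", "))
  }
  set.seed(cfg$seed)
  pep <- data.frame(
    accession = rep(acc, lengths(target_peptides[acc])),
    peptide = unlist(target_peptides[acc], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  sig <- cfg$peptide_ionization_sigma
  heavy_eff <- if (sig > 0)
    stats::rlnorm(nrow(pep), -sig^2 / 2, sig) else rep(1, nrow(pep))
  heavy <- cfg$heavy_area_base * heavy_eff

  S <- cfg$spike_fmol_per_ug
  Y <- cfg$yield_ug_per_mg
  conds <- unique(conc$condition)
  out <- vector("list", length(conds) * cfg$n_samples)
  k <- 0L
  for (cond in conds) {
    cvec <- stats::setNames(conc$umol_per_kg[conc$condition == cond],
                            conc$accession[conc$condition == cond])
    r_true <- cvec[pep$accession] / (S * Y * 1e-3)
    for (i in seq_len(cfg$n_samples)) {
      drift <- .mult_noise_gauss(1L, cfg$tic_drift_cv)
      eps <- .mult_noise_gauss(nrow(pep), cfg$prm_cv)
      k <- k + 1L
      out[[k]] <- data.frame(
        sample_id = sprintf("%s_%02d", cond, i),
        condition = cond,
        accession = pep$accession,
        peptide = pep$peptide,
        light_area = unname(r_true) * heavy * drift * eps,
        heavy_area = heavy,
        sample_tic = cfg$tic_base * drift,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
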