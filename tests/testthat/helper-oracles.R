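# Independent brute-force oracles used to validate the package's
# implementations. These deliberately share no code with the package: each
# re-derives its answer from first principles on small inputs.

# Enumerate every substring that is a valid tryptic peptide with at most
# `mc` missed cleavages, by scanning all (start, end) pairs.
oracle_tryptic_enumeration <- function(sequence, mc) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  is_cut <- function(i) {
    # cut between position i and i+1
    i >= 1 && i < n && chars[i] %in% c("K", "R") && chars[i + 1] != "P"
  }
  out <- character(0)
  for (start in 1:n) {
    if (!(start == 1 || is_cut(start - 1))) next
    for (end in start:n) {
      if (!(end == n || is_cut(end))) next
      internal <- 0
      if (end > start)
        internal <- sum(vapply((start):(end - 1), is_cut, logical(1)))
      if (internal <= mc) out <- c(out, substr(sequence, start, end))
    }
  }
  unique(out)
}

# Observable-peptide count: full enumeration at 0 missed cleavages plus a
# length filter on distinct peptides.
oracle_observable_count <- function(sequence, lo = 7, hi = 30) {
  peps <- oracle_tryptic_enumeration(sequence, 0)
  sum(nchar(peps) >= lo & nchar(peps) <= hi)
}

# Literal BH step-up: q_i = min over j with p_(j) >= p_(i) of p_(j)*m/rank(j).
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranks <- rank(p, ties.method = "first")
  sapply(seq_len(m), function(i) {
    candidates <- sapply(seq_len(m), function(j) {
      if (p[ord[j]] >= p[i]) p[ord[j]] * m / j else NA_real_
    })
    min(1, min(candidates, na.rm = TRUE))
  })
}

# Venn region of each element by direct membership testing.
oracle_venn_regions <- function(sets) {
  universe <- unique(unlist(sets))
  assign_region <- sapply(universe, function(x) {
    paste(names(sets)[sapply(sets, function(s) x %in% s)], collapse = "&")
  })
  split(universe, assign_region)
}

# Small deterministic TMT fixture: spike-in ECC proteins with reference
# WT-EDL concentrations as ground truth.
ecc_tmt_fixture <- function(cfg = sim_config(), fold_change = c(Ryr1 = 0.4)) {
  db <- build_spikein_db()
  ref <- ecc_reference_concentrations(muscle = "EDL", genotype = "WT")
  truth <- ground_truth(setNames(ref$mean_umol_per_kg, ref$accession),
                        fold_change = fold_change)
  list(db = db, truth = truth, psm = simulate_tmt(db, truth, cfg))
}
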