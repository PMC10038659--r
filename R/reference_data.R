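# Bundled reference data for the ECC case study: published concentrations of
# excitation-contraction-coupling proteins in mouse EDL, soleus and
# extraocular muscle (WT and dHT Ryr1-mutant genotypes), the oligomer map,
# and the PRM target peptides.

#' Reference ECC protein concentrations in mouse muscle
#'
#' PRM/SID-derived concentrations (mean ± SD, µmol/kg wet weight, n = 5 mice)
#' of nine excitation-contraction-coupling proteins in EDL, soleus and
#' extraocular (EOM) muscle from wild-type (WT) and dHT Ryr1-mutant mice.
#' Orai1 is below the mass-spectrometric detection level in soleus
#' (`detected = FALSE`). These values serve as worked-example inputs for the
#' stoichiometry stage and as ground truth for the simulation-based
#' parameter-recovery checks.
#'
#' @param muscle Optional filter: `"EDL"`, `"soleus"`, `"EOM"`.
#' @param genotype Optional filter: `"WT"`, `"dHT"`.
#' @return `data.frame`: `accession` (gene symbol), `muscle`, `genotype`,
#'   `condition` (`muscle.genotype`), `mean_umol_per_kg`, `sd_umol_per_kg`,
#'   `detected`.
#' @export
ecc_reference_concentrations <- function(muscle = NULL, genotype = NULL) {
  g <- c("Ryr1", "Cacna1s", "Stac3", "Jsrp1", "Asph", "Trdn", "Jph1",
         "Stim1", "Orai1")
  tab <- list(
    #          Ryr1  Cacna1s Stac3 Jsrp1 Asph  Trdn  Jph1  Stim1 Orai1
    EDL.WT  = c(1.29, 0.56, 0.62, 0.42, 0.21, 0.96, 0.71, 0.46, 0.11),
    EDL.dHT = c(0.86, 0.49, 0.53, 0.40, 0.26, 0.79, 0.58, 0.48, 0.13),
    soleus.WT  = c(0.49, 0.18, 0.22, 0.32, 0.30, 0.16, 0.29, 0.55, NA),
    soleus.dHT = c(0.40, 0.16, 0.20, 0.29, 0.35, 0.13, 0.25, 0.56, NA),
    EOM.WT  = c(0.59, 0.21, 0.17, 0.35, 0.82, 0.23, 0.24, 1.35, 0.16),
    EOM.dHT = c(0.35, 0.19, 0.15, 0.35, 1.00, 0.22, 0.23, 1.42, 0.17)
  )
  sds <- list(
    EDL.WT  = c(0.07, 0.03, 0.07, 0.03, 0.01, 0.18, 0.09, 0.02, 0.01),
    EDL.dHT = c(0.01, 0.01, 0.06, 0.01, 0.01, 0.06, 0.04, 0.03, 0.02),
    soleus.WT  = c(0.02, 0.01, 0.02, 0.01, 0.02, 0.03, 0.02, 0.03, NA),
    soleus.dHT = c(0.002, 0.002, 0.01, 0.03, 0.03, 0.01, 0.01, 0.03, NA),
    EOM.WT  = c(0.02, 0.01, 0.01, 0.01, 0.03, 0.01, 0.01, 0.03, 0.03),
    EOM.dHT = c(0.01, 0.004, 0.01, 0.02, 0.03, 0.01, 0.01, 0.09, 0.01)
  )
  conds <- names(tab)
  out <- do.call(rbind, lapply(conds, function(cn) {
    parts <- strsplit(cn, ".", fixed = TRUE)[[1L]]
    data.frame(accession = g, muscle = parts[1L], genotype = parts[2L],
               condition = cn, mean_umol_per_kg = tab[[cn]],
               sd_umol_per_kg = sds[[cn]], detected = !is.na(tab[[cn]]),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(muscle)) out <- out[out$muscle %in% muscle, , drop = FALSE]
  if (!is.null(genotype)) out <- out[out$genotype %in% genotype, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Oligomer map for ECC complexes
#'
#' Subunits per functional complex: RyR1 assembles as a homotetramer and
#' Orai1 as a hexameric channel; all other proteins are treated as monomers.
#'
#' @return Named integer vector: accession -> subunit count.
#' @export
ecc_oligomer_map <- function() {
  c(Ryr1 = 4L, Orai1 = 6L)
}

#' PRM target peptides for the ECC proteins
#'
#' Proteotypic tryptic peptides used as heavy-labelled references for Ryr1,
#' Cacna1s (DHPRalpha1s), Stim1 and Orai1. For the remaining five proteins
#' (Stac3, Jsrp1, Asph, Trdn, Jph1) no reference peptides are bundled from
#' measurement; the entries are synthetic tryptic peptides invented for
#' simulation only.
#'
#' @return Named list: accession -> character vector of peptides.
#' @export
ecc_target_peptides <- function() {
  list(
    Ryr1 = c("AGDVQSGGSDQER", "GPHLVGPSR", "SNQDLITENLLPGR", "TLLWTFIK",
             "VVAEEEQLR"),
    Cacna1s = c("AIWAEYDPEAK", "GEGIPTTAK", "TGGLFGQVDNFLER"),
    Stim1 = c("LISVEDLWK", "AIDTVIFGPPIITR", "ITEPQIGIGSQR", "LSFEAVR",
              "YAEEEIEQVR"),
    Orai1 = c("QFQELNELAEFAR", "IQDQIDHR", "SLVSHK"),
    # synthetic stand-in peptides (no measured references bundled)
    Stac3 = c("GDLSSFDSLAK", "VTELYNDFR", "AEGLTPEQR"),
    Jsrp1 = c("LDSGDVAELR", "TQPSAEVLK", "GFDEESLR"),
    Asph  = c("ETGDWLQK", "SYEEGLSR", "NVDLSGAK"),
    Trdn  = c("VSDFTEQLK", "GEAQPDLSR", "TLNDESIR"),
    Jph1  = c("SGFDELQR", "AVSEDGLTK", "YQDSLNAR")
  )
}

#' Build a synthetic protein database embedding target peptides
#'
#' Concatenates each protein's target peptides (all fully tryptic, ending in
#' K/R, none starting with P) into a synthetic sequence, so every target
#' peptide is recoverable by zero-missed-cleavage tryptic digestion. To give
#' the carriers realistic peptide counts (the real ECC proteins are large —
#' RyR1 alone is ~5000 residues), each sequence is padded with additional
#' random tryptic peptides. A stand-in for real sequences, intended for
#' simulation.
#'
#' @param target_peptides Named list as from [ecc_target_peptides()].
#' @param pad_peptides Random tryptic filler peptides appended per protein
#'   (default 20; set 0 for target-only sequences).
#' @param seed Seed for the filler peptides.
#' @return Protein database `data.frame` (`accession`, `description`,
#'   `sequence`).
#' @export
build_spikein_db <- function(target_peptides = ecc_target_peptides(),
                             pad_peptides = 20L, seed = 1L) {
  pad <- function(n) {
    if (n == 0L) return("")
    lens <- sample(7:16, n, replace = TRUE)
    body <- setdiff(names(.aa_freq), c("K", "R", "P"))
    paste(vapply(lens, function(L) {
      paste0(paste(sample(body, L - 1L, replace = TRUE), collapse = ""),
             sample(c("K", "R"), 1L))
    }, character(1)), collapse = "")
  }
  set.seed(as.integer(seed))
  seqs <- vapply(target_peptides, function(p)
    paste0(paste(p, collapse = ""), pad(as.integer(pad_peptides))),
    character(1))
  data.frame(
    accession = names(target_peptides),
    description = sprintf("synthetic spike-in target carrier (%s)",
                          names(target_peptides)),
    sequence = unname(seqs),
    stringsAsFactors = FALSE
  )
}
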