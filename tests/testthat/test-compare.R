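test_that("Venn partition is exhaustive, disjoint and matches brute force", {
  disjoint <- venn_partition(list(a = c("x"), b = c("y"), c = c("z")))
  expect_equal(unname(disjoint$counts[c("a&b", "a&c", "b&c", "a&b&c")]),
               rep(0L, 4))

  sets <- list(S1 = c("A", "B"), S2 = c("B", "C"), S3 = c("B"))
  part <- venn_partition(sets)
  expect_identical(part$regions[["S1&S2&S3"]], "B")
  oracle <- oracle_venn_regions(sets)
  for (region in names(oracle)) {
    expect_setequal(part$regions[[region]], oracle[[region]])
  }

  set.seed(31)
  for (i in 1:6) {
    rand <- list(a = sample(letters, 8), b = sample(letters, 12),
                 c = sample(letters, 5))
    p <- venn_partition(rand)
    # counts sum to the union; regions are pairwise disjoint
    expect_equal(sum(p$counts), length(unique(unlist(rand))))
    all_members <- unlist(p$regions, use.names = FALSE)
    expect_equal(anyDuplicated(all_members), 0)
  }
  expect_error(venn_partition(list(1:2, 1:2, 1:2, 1:2)), "2 or 3")
})

test_that("shared direction is the intersection across comparisons", {
  sets <- list(
    comparison_set("EDL", up = c("Asph", "Camk2d"), down = c("Ryr1", "Col1a2")),
    comparison_set("soleus", up = c("Asph"), down = c("Ryr1")),
    comparison_set("EOM", up = c("Asph", "Hspb6"), down = c("Ryr1", "Myh13"))
  )
  # RyR1 down-regulation as the unique shared signature
  expect_identical(shared_direction(sets, "down"), "Ryr1")
  expect_identical(shared_direction(sets, "up"), "Asph")
  none <- list(comparison_set("x", "A", "B"), comparison_set("y", "C", "D"))
  expect_identical(shared_direction(none, "up"), character(0))
  for (s in sets) {
    expect_true(all(shared_direction(sets, "down") %in% s$down))
  }
  expect_error(comparison_set("bad", up = "A", down = "A"), "disjoint")
})

test_that("display matrices: volcano coordinates and z-scored heatmap", {
  ch <- c("c1", "c2", "c3", "c4")
  des <- channel_design(setNames(c("WT", "WT", "dHT", "dHT"), ch))
  quants <- data.frame(accession = c("P1", "P2", "P3"), n_peptides = 3L)
  quants[ch] <- as.data.frame(rbind(c(4, 4.4, 8, 8.8),
                                    c(2, 2.2, 4, 4.4),
                                    c(16, 8.8, 8, 4.4)))
  attr(quants, "channels") <- ch
  results <- data.frame(
    accession = c("P1", "P2", "P3"),
    log2fc = c(1, 0, -1), p_value = c(0.001, 1, 0),
    significant = c(TRUE, FALSE, TRUE), stringsAsFactors = FALSE
  )
  disp <- build_display_matrices(results, quants, des)
  # ratio 1 -> volcano x = 0 exactly; p = 0 capped and flagged
  expect_equal(disp$volcano$log2fc[2], 0)
  expect_equal(disp$volcano$neg_log10_p[3], 300)
  expect_true(disp$volcano$capped[3])
  expect_equal(disp$volcano$neg_log10_p[1], 3)
  # rows restricted to significant proteins, z-scored to mean 0 / sd 1
  expect_setequal(rownames(disp$heatmap), c("P1", "P3"))
  expect_equal(unname(rowMeans(disp$heatmap)), c(0, 0))
  expect_equal(unname(apply(disp$heatmap, 1, sd)), c(1, 1))
})

test_that("heatmap row order follows average-linkage 1-Pearson clustering", {
  ch <- sprintf("c%d", 1:6)
  des <- channel_design(setNames(rep(c("WT", "dHT"), each = 3), ch))
  base <- c(1, 2, 3, 4, 5, 6)
  quants <- data.frame(accession = c("P1", "P2", "P3"), n_peptides = 2L)
  # P1 and P2 perfectly correlated, P3 anti-correlated:
  # d(P1,P2) = 0, d(P1,P3) = d(P2,P3) = 2
  quants[ch] <- as.data.frame(rbind(2^base, 2^(base * 2), 2^rev(base)))
  attr(quants, "channels") <- ch
  results <- data.frame(accession = c("P1", "P2", "P3"),
                        log2fc = 0, p_value = 0.5, significant = TRUE)
  disp <- build_display_matrices(results, quants, des)
  # hand dendrogram: P1 and P2 merge first (height 0), P3 joins at height 2
  ord <- disp$row_order
  expect_true(which(ord == "P3") %in% c(1, 3))
  expect_equal(abs(which(ord == "P1") - which(ord == "P2")), 1)
  d <- as.dist(1 - cor(t(log2(as.matrix(quants[, ch])))))
  hc <- hclust(d, method = "average")
  expect_equal(sort(hc$height), c(0, 2), tolerance = 1e-12)
})

test_that("end-to-end shared down-regulation is recovered on designed truth", {
  # three simulated muscles share a single designed down-regulated protein;
  # a background proteome keeps the global-normalization assumption (most
  # proteins unchanged) realistic
  db <- rbind(build_spikein_db(),
              generate_protein_db(60, 300, seed = 17, accession_prefix = "BKG"))
  peps <- tryptic_peptide_table(db)
  ref <- ecc_reference_concentrations(muscle = "EDL", genotype = "WT")
  set.seed(18)
  conc <- c(setNames(ref$mean_umol_per_kg, ref$accession),
            setNames(rlnorm(60, log(0.5), 1),
                     grep("^BKG", db$accession, value = TRUE)))
  hits <- sapply(1:10, function(s) {
    sets <- lapply(1:3, function(m) {
      fc <- c(Ryr1 = 0.4)
      if (m == 2) fc <- c(fc, Asph = 1.8)
      truth <- ground_truth(conc, fold_change = fc)
      cfg <- sim_config(seed = s * 100 + m)
      psm <- simulate_tmt(db, truth, cfg, peptides = peps)
      q <- rollup_proteins(normalize_channels(psm)$table, db)
      res <- differential_abundance(q, channel_design(cfg$design))
      sig <- res[res$significant, ]
      comparison_set(paste0("m", m),
                     up = sig$accession[sig$ratio > 1],
                     down = sig$accession[sig$ratio < 1])
    })
    identical(shared_direction(sets, "down"), "Ryr1")
  })
  expect_gte(mean(hits), 0.95)
})
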