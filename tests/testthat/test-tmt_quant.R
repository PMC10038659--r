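make_psm <- function(intensities, accession = "P1", peptide = NULL) {
  M <- matrix(intensities, ncol = 2, byrow = TRUE)
  n <- nrow(M)
  if (is.null(peptide)) peptide <- sprintf("PEPTIDEK%d", seq_len(n))
  df <- data.frame(accession = rep_len(accession, n), peptide = peptide,
                   A = M[, 1], B = M[, 2], stringsAsFactors = FALSE)
  attr(df, "channels") <- c("A", "B")
  df
}

test_that("reporter impurity correction solves the mixing system", {
  psm <- make_psm(c(100, 0, 50, 50))
  ident <- correct_reporters(psm, diag(2))
  expect_equal(ident$A, psm$A)
  expect_equal(ident$B, psm$B)

  # 5% symmetric leakage; hand 2x2 inverse of [[.95,.05],[.05,.95]]
  imp <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
  inv <- matrix(c(0.95, -0.05, -0.05, 0.95), 2, 2) / (0.95^2 - 0.05^2)
  expect_warning(corr <- correct_reporters(psm, imp), "clipped")
  hand <- t(inv %*% t(as.matrix(psm[, c("A", "B")])))
  hand[hand < 0] <- 0
  expect_equal(as.matrix(corr[, c("A", "B")]), hand, ignore_attr = TRUE)

  # round trip: re-mixing reproduces the observed intensities (rows with no
  # negative-clipping)
  clean <- make_psm(c(100, 40, 60, 60))
  corr2 <- correct_reporters(clean, imp)
  remixed <- t(imp %*% t(as.matrix(corr2[, c("A", "B")])))
  expect_equal(remixed, as.matrix(clean[, c("A", "B")]), ignore_attr = TRUE)

  expect_error(correct_reporters(psm, matrix(1, 2, 2)), "singular")
})

test_that("channel normalization equalizes totals and conserves intensity", {
  equal <- make_psm(c(100, 100, 50, 50))
  out <- normalize_channels(equal)
  expect_equal(unname(out$factors), c(1, 1))

  psm <- make_psm(c(150, 80, 50, 20))  # totals (200, 100)
  out <- normalize_channels(psm)
  expect_equal(unname(out$factors), c(0.75, 1.5))
  expect_equal(colSums(as.matrix(out$table[, c("A", "B")])), c(A = 150, B = 150))
  expect_equal(sum(as.matrix(out$table[, c("A", "B")])),
               sum(as.matrix(psm[, c("A", "B")])))

  zero <- make_psm(c(10, 0, 20, 0))
  expect_error(normalize_channels(zero), "non-positive total")
})

test_that("protein roll-up sums channels and counts distinct peptides", {
  db <- data.frame(accession = "P1", description = "",
                   sequence = "AAAAAAAKAAAAAAAR", stringsAsFactors = FALSE)
  single <- make_psm(c(10, 20), peptide = "AAAAAAAK")
  r1 <- rollup_proteins(single, db)
  expect_equal(unlist(r1[, c("A", "B")], use.names = FALSE), c(10, 20))

  two <- make_psm(c(10, 20, 1, 2), peptide = c("AAAAAAAK", "AAAAAAAR"))
  r2 <- rollup_proteins(two, db)
  expect_equal(unlist(r2[, c("A", "B")], use.names = FALSE), c(11, 22))
  expect_equal(r2$n_peptides, 2)
  # iBAQ: total intensity 33 over 2 observable peptides
  expect_equal(r2$ibaq, 33 / 2)

  # permuting rows leaves the roll-up invariant
  r2b <- rollup_proteins(two[c(2, 1), ], db)
  expect_equal(r2, r2b)

  expect_error(rollup_proteins(make_psm(c(1, 1), accession = "NOPE"), db),
               "missing from the protein database")
})

test_that("observable-peptide count matches exhaustive enumeration", {
  expect_equal(count_observable_peptides("AAAAAAA"), 1)
  # "AAAAAAK" (7) observable, trailing "AAAAAA" (6) too short
  expect_equal(count_observable_peptides("AAAAAAKAAAAAA"), 1)
  set.seed(7)
  for (i in 1:6) {
    s <- generate_protein_db(1, 100, seed = 20 + i)$sequence
    expect_equal(count_observable_peptides(s), oracle_observable_count(s))
  }
})

toy_quants <- function(n = 20, seed = 42) {
  set.seed(seed)
  ch <- tmt10_channels()
  mu <- runif(n, 8, 20)
  fc <- c(rep(0, n - 4), c(-2, -1, 1, 2))
  sd <- sqrt(exp(rnorm(n, -2, 0.8)))
  L <- t(sapply(seq_len(n), function(i)
    c(rnorm(5, mu[i], sd[i]), rnorm(5, mu[i] + fc[i], sd[i]))))
  q <- data.frame(accession = sprintf("P%02d", 1:n), n_peptides = 5L,
                  stringsAsFactors = FALSE)
  q[ch] <- as.data.frame(2^L)
  attr(q, "channels") <- ch
  q
}

test_that("moderated t matches a direct transcription of the posterior formula", {
  q <- toy_quants()
  des <- channel_design(setNames(rep(c("WT", "dHT"), each = 5),
                                 tmt10_channels()))
  res <- moderated_t(q, des)
  hyper <- attr(res, "hyperparams")

  # independent transcription from the log2 matrix
  L <- log2(as.matrix(q[, tmt10_channels()]))
  for (i in c(1, 7, 18, 20)) {
    x1 <- L[i, 1:5]; x2 <- L[i, 6:10]
    delta <- mean(x2) - mean(x1)
    s2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / 8
    s2_post <- (hyper$d0 * hyper$s0_sq + 8 * s2) / (hyper$d0 + 8)
    t_hand <- delta / sqrt(s2_post * (1 / 5 + 1 / 5))
    expect_equal(res$t_moderated[i], t_hand, tolerance = 1e-12)
    expect_equal(res$p_value[i],
                 2 * pt(-abs(t_hand), hyper$d0 + 8), tolerance = 1e-12)
    expect_equal(res$ratio[i], 2^delta, tolerance = 1e-12)
  }
})

test_that("moderated t limiting cases: ordinary t at d0 = 0, common variance at d0 = Inf", {
  q <- toy_quants(seed = 11)
  des <- channel_design(setNames(rep(c("WT", "dHT"), each = 5),
                                 tmt10_channels()))
  L <- log2(as.matrix(q[, tmt10_channels()]))

  res0 <- moderated_t(q, des, hyperparams = list(d0 = 0, s0_sq = 1))
  ordinary <- apply(L, 1, function(x)
    t.test(x[6:10], x[1:5], var.equal = TRUE)$statistic)
  expect_equal(res0$t_moderated, unname(ordinary), tolerance = 1e-10)
  expect_equal(unique(res0$df_total), 8)

  resInf <- moderated_t(q, des, hyperparams = list(d0 = Inf, s0_sq = 0.25))
  delta <- rowMeans(L[, 6:10]) - rowMeans(L[, 1:5])
  expect_equal(resInf$t_moderated,
               unname(delta / sqrt(0.25 * 0.4)), tolerance = 1e-12)
  expect_true(all(is.infinite(resInf$df_total)))
})

test_that("moderated t agrees with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  q <- toy_quants(seed = 3)
  des <- channel_design(setNames(rep(c("WT", "dHT"), each = 5),
                                 tmt10_channels()))
  res <- moderated_t(q, des)
  hyper <- attr(res, "hyperparams")

  L <- log2(as.matrix(q[, tmt10_channels()]))
  design_mat <- cbind(1, rep(0:1, each = 5))
  fit <- limma::eBayes(limma::lmFit(L, design_mat))
  expect_equal(hyper$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(hyper$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_moderated, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(res$p_value, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("moderated t requires replication and excludes zero intensities", {
  q <- toy_quants(seed = 5)
  labels <- setNames(c("WT", rep("dHT", 9)), tmt10_channels())
  expect_error(moderated_t(q, channel_design(labels)), ">= 2 channels")

  q$`126`[3] <- 0
  des <- channel_design(setNames(rep(c("WT", "dHT"), each = 5),
                                 tmt10_channels()))
  expect_message(res <- moderated_t(q, des), "excluded")
  expect_equal(nrow(res), 19)
  expect_equal(attr(res, "n_excluded"), 1)
})

test_that("scale equivariance: a global intensity factor changes nothing", {
  q <- toy_quants(seed = 9)
  des <- channel_design(setNames(rep(c("WT", "dHT"), each = 5),
                                 tmt10_channels()))
  res1 <- moderated_t(q, des)
  q2 <- q
  q2[tmt10_channels()] <- q2[tmt10_channels()] * 1000
  res2 <- moderated_t(q2, des)
  expect_equal(res1$ratio, res2$ratio, tolerance = 1e-9)
  expect_equal(res1$t_moderated, res2$t_moderated, tolerance = 1e-9)
  expect_equal(res1$p_value, res2$p_value, tolerance = 1e-9)
})

test_that("BH adjustment matches the literal step-up rule and is monotone", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(13)
  for (i in 1:5) {
    p <- runif(sample(3:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("significance filter applies the q, fold and peptide-count rules", {
  res <- data.frame(
    accession = sprintf("P%d", 1:6),
    ratio = c(0.40, 1.00, 1.25, 1.15, 0.75, 1.30),
    q_value = c(3.97e-5, 1e-9, 0.01, 0.001, 0.06, 0.04),
    n_peptides = c(5L, 10L, 2L, 8L, 9L, 1L),
    stringsAsFactors = FALSE
  )
  out <- filter_significant(res)
  # brute-force rule application
  keep <- res$q_value < 0.05 & abs(res$ratio - 1) >= 0.2 & res$n_peptides >= 2
  expect_identical(out$table$accession, res$accession[keep])
  # the strongly downregulated 5-peptide protein survives, direction down
  expect_true("P1" %in% out$table$accession)
  expect_equal(out$n_down, 1)
  expect_equal(out$n_up, 1)
  # ratio exactly 1 is removed regardless of q
  expect_false("P2" %in% out$table$accession)
})
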