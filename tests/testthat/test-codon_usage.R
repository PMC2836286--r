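test_that("codon counting is exact, skips ambiguity and is additive", {
  m <- count_codons(c(g1 = "ATGATGTAA"))
  expect_equal(m[1, "ATG"], c(ATG = 2L), ignore_attr = TRUE)
  expect_equal(m[1, "TAA"], c(TAA = 1L), ignore_attr = TRUE)
  expect_equal(sum(m), 3L)
  # codon containing N is skipped and reduces the total by one
  mn <- count_codons(c(g = "ATGANGTTT"))
  expect_equal(sum(mn), 2L)
  # additivity
  set.seed(5)
  a <- random_cds(50L); b <- random_cds(70L)
  expect_equal(colSums(count_codons(c(x = a, y = b))),
               colSums(count_codons(c(z = paste0(a, b)))) )
  expect_error(count_codons(character()), "no coding")
  expect_error(count_codons("ATGA"), "divisible")
})

test_that("RSCU matches the family-share formula and sums to family size", {
  v <- setNames(rep(0L, 64L), colnames(count_codons(c(x = "ATG"))))
  v["TTT"] <- 3L; v["TTC"] <- 1L
  r <- rscu(v)
  expect_equal(r[1, "TTT"], 1.5, ignore_attr = TRUE)
  expect_equal(r[1, "TTC"], 0.5, ignore_attr = TRUE)
  # 4-fold family (4,0,0,0) -> (4,0,0,0)
  v2 <- setNames(rep(0L, 64L), names(v))
  v2["GGT"] <- 4L
  r2 <- rscu(v2)
  expect_equal(unname(r2[1, c("GGT", "GGC", "GGA", "GGG")]), c(4, 0, 0, 0))
  # uniform usage in every family -> all RSCU 1 for present families
  v3 <- setNames(rep(1L, 64L), names(v))
  r3 <- rscu(v3)
  expect_true(all(abs(r3 - 1) < 1e-12))
  # family-sum property on random genes
  set.seed(11)
  cds <- vapply(1:50, function(i) random_cds(sample(80:200, 1L)), "")
  names(cds) <- paste0("g", 1:50)
  rs <- rscu(count_codons(cds))
  fams <- split(colnames(rs), Biostrings::GENETIC_CODE[colnames(rs)])
  for (fam in fams) {
    s <- rowSums(rs[, fam, drop = FALSE])
    expect_true(all(abs(s - length(fam)) < 1e-9 | s == 0))
  }
})

test_that("GC3s/GT3s are third-position fractions over synonymous codons", {
  ggg <- count_codons(c(g = strrep("GGG", 30L)))
  tp <- gc3s_gt3s(ggg)
  expect_equal(tp$gc3s, 1.0)
  expect_equal(tp$gt3s, 1.0)
  gga <- count_codons(c(g = strrep("GGA", 30L)))
  tp2 <- gc3s_gt3s(gga)
  expect_equal(tp2$gc3s, 0.0)
  expect_equal(tp2$gt3s, 0.0)
  # hand-count oracle on a mixed toy gene (ATG and TGG excluded)
  toy <- "ATGGGGTTTACCTGGGAA"  # ATG | GGG | TTT | ACC | TGG | GAA
  cnt <- count_codons(c(t = toy))
  tp3 <- gc3s_gt3s(cnt)
  # synonymous codons: GGG(G), TTT(T), ACC(C), GAA(A) -> GC3 2/4, GT3 2/4
  expect_equal(tp3$gc3s, 0.5)
  expect_equal(tp3$gt3s, 0.5)
  expect_equal(tp3$syn_codons, 4L)
})

test_that("correspondence analysis matches an independent oracle", {
  skip_if_not_installed("MASS")
  set.seed(21)
  for (rep in 1:5) {
    m <- matrix(rgamma(80L, shape = 2), 10L, 8L)
    ca <- correspondence_analysis(m, k = 4L)
    cr <- suppressWarnings(MASS::corresp(m, nf = 4L))
    oracle <- cr$rscore %*% diag(cr$cor)
    for (j in 1:4) {
      err <- min(max(abs(ca$row_coords[, j] - oracle[, j])),
                 max(abs(ca$row_coords[, j] + oracle[, j])))
      expect_lt(err, 1e-10)
    }
    expect_equal(sum(ca$inertia_pct), 100, tolerance = 1e-9)
  }
})

test_that("CA respects identical rows, permutation invariance and degeneracy", {
  set.seed(2)
  m <- matrix(rgamma(40L, 2), 5L, 8L)
  m[2, ] <- m[1, ]
  ca <- correspondence_analysis(m)
  expect_equal(ca$row_coords[1, ], ca$row_coords[2, ], tolerance = 1e-12)
  # permutation of rows permutes coordinates (up to axis sign)
  perm <- c(3, 1, 5, 2, 4)
  ca_p <- correspondence_analysis(m[perm, ])
  for (j in seq_len(ca$k)) {
    direct <- ca$row_coords[perm, j]
    err <- min(max(abs(ca_p$row_coords[, j] - direct)),
               max(abs(ca_p$row_coords[, j] + direct)))
    expect_lt(err, 1e-10)
  }
  # all-identical matrix: zero inertia, zero coordinates
  m0 <- matrix(1, 4L, 6L)
  ca0 <- correspondence_analysis(m0)
  expect_true(all(ca0$row_coords == 0))
})

test_that("axis-trait correlations behave at the extremes", {
  set.seed(8)
  m <- matrix(rgamma(200L, 2), 20L, 10L)
  ca <- correspondence_analysis(m)
  r <- axis_trait_correlation(ca, ca$row_coords[, 1L])
  expect_equal(unname(r[1L]), 1, tolerance = 1e-12)
  expect_error(axis_trait_correlation(ca, rep(1, 20L)), "zero variance")
  # independent noise decorrelates
  big <- matrix(rgamma(5900L, 2), 100L)
  ca_big <- correspondence_analysis(big)
  rn <- axis_trait_correlation(ca_big, rnorm(100L))
  expect_true(all(abs(rn) < 0.3))
})

test_that("within-family strand chi-square recovers the closed form", {
  codons <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                  paste0), c("A","C","G","T"), paste0))
  lead <- setNames(rep(0L, 64L), sort(codons))
  lag <- lead
  lead["TTT"] <- 30L; lead["TTC"] <- 70L
  lag["TTT"] <- 10L; lag["TTC"] <- 90L
  out <- strand_codon_chisq(lead, lag)
  phe <- out[out$codon == "TTT", ]
  expect_equal(phe$chisq, 12.5, tolerance = 1e-12)
  expect_equal(phe$enriched, "leading")
  expect_true(phe$significant)

  # identical usage on both strands: nothing flagged
  set.seed(4)
  cds <- vapply(1:30, function(i) random_cds(150L), "")
  names(cds) <- paste0("g", 1:30)
  cnt <- colSums(count_codons(cds))
  out2 <- strand_codon_chisq(cnt, cnt)
  expect_false(any(out2$significant))
})

test_that("planted third-position bias flags G/T-ending codons on the leading strand", {
  cfg <- simulation_config(seed = 77, genome_length = 120000L,
                           gene_count = 90L, gene_length_codons = 200L,
                           delta = 0.15, remnant_count = 0L)
  sim <- simulate_genome(cfg)
  cds <- extract_cds(sim$genome, sim$annotations, min_aa = 100L)
  cnt <- count_codons(cds)
  cls <- sim$truth$genes$strand_class[match(cds$gene_id,
                                            sim$truth$genes$gene_id)]
  res <- strand_codon_chisq(cnt[cls == "leading", , drop = FALSE],
                            cnt[cls == "lagging", , drop = FALSE])
  flagged <- res[res$significant & res$enriched == "leading", ]
  expect_gt(nrow(flagged), 5L)
  third <- substr(flagged$codon, 3L, 3L)
  expect_gt(mean(third %in% c("G", "T")), 0.9)
})
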