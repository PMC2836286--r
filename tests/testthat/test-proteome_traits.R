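test_that("amino-acid usage is a proper frequency vector with pooling", {
  u <- amino_acid_usage("AAAA")
  expect_equal(unname(u["A"]), 1)
  expect_equal(sum(u), 1)
  u20 <- amino_acid_usage("ACDEFGHIKLMNPQRSTVWY")
  expect_true(all(abs(u20 - 0.05) < 1e-12))
  # pooled set equals the residue-count-weighted mean
  p1 <- "AAAC"; p2 <- "DDDDDDDD"
  pooled <- amino_acid_usage(c(p1, p2))
  w <- (amino_acid_usage(p1) * 4 + amino_acid_usage(p2) * 8) / 12
  expect_equal(as.numeric(pooled), as.numeric(w), tolerance = 1e-12)
  # nonstandard residues excluded
  ux <- amino_acid_usage("AXXA")
  expect_equal(unname(ux["A"]), 1)
  expect_error(amino_acid_usage(character()), "no protein")
})

test_that("standardization is a ratio to the reference with a neutral identity", {
  set.seed(3)
  ref <- amino_acid_usage(random_peptide(2000L))
  expect_true(all(abs(standardize_usage(ref, ref) - 1) < 1e-12))
  org <- ref
  org["S"] <- 0.08
  ref2 <- ref
  ref2["S"] <- 0.04
  expect_equal(unname(standardize_usage(org, ref2)["S"]), 2.0)
  ref0 <- ref; ref0["W"] <- 0
  expect_error(standardize_usage(org, ref0), "zero")
})

test_that("planted amino-acid depletion is recovered through standardization", {
  base <- simulation_config(seed = 61, genome_length = 60000L,
                            gene_count = 40L, gene_length_codons = 150L,
                            remnant_count = 0L)
  dep <- simulation_config(seed = 61, genome_length = 60000L,
                           gene_count = 40L, gene_length_codons = 150L,
                           remnant_count = 0L, aa_shift = c(T = 0.3))
  prot_of <- function(cfg) {
    sim <- simulate_genome(cfg)
    extract_cds(sim$genome, sim$annotations, min_aa = 50L)$protein
  }
  ref <- amino_acid_usage(prot_of(base))
  org <- amino_acid_usage(prot_of(dep))
  std <- standardize_usage(org, ref)
  expect_lt(unname(std["T"]), 1)
})

test_that("single-linkage clustering on usage vectors behaves canonically", {
  mk <- function(v) setNames(v, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  base <- rep(1, 20)
  u1 <- mk(base); u2 <- mk(base)
  u3 <- mk(c(10, base[-1]))
  cl <- cluster_usage(list(a = u1, b = u2, c = u3))
  expect_equal(cl$tree$height[1L], 0)
  expect_error(cluster_usage(list(a = u1)), "two organisms")
  dup <- list(a = u1, a = u2)
  expect_error(cluster_usage(dup), "unique")
  # 1-D single linkage: points 0, 1, 10 merge (0,1) first, then at 9
  v0 <- mk(base); v1 <- v0; v9 <- v0
  v1["A"] <- v1["A"] + 1; v9["A"] <- v9["A"] + 10
  cl2 <- cluster_usage(list(x = v0, y = v1, z = v9))
  expect_equal(cl2$tree$height, c(1, 9), tolerance = 1e-12)
  # planted blocks split at the top
  set.seed(10)
  blockA <- lapply(1:4, function(i) mk(base + runif(20, 0, 0.05)))
  blockB <- lapply(1:4, function(i) mk(c(6, base[-1]) + runif(20, 0, 0.05)))
  names(blockA) <- paste0("a", 1:4); names(blockB) <- paste0("b", 1:4)
  cl3 <- cluster_usage(c(blockA, blockB))
  top <- stats::cutree(cl3$tree, k = 2)
  expect_equal(length(unique(top[paste0("a", 1:4)])), 1L)
  expect_equal(length(unique(top[paste0("b", 1:4)])), 1L)
  expect_false(top[["a1"]] == top[["b1"]])
})

test_that("GRAVY and aromaticity reproduce scale constants", {
  expect_equal(gravy("AAAA"), 1.8)
  expect_equal(gravy("RRRR"), -4.5)
  expect_equal(gravy("AR"), -1.35)
  expect_equal(aromaticity("FYWA"), 0.75)
  expect_equal(aromaticity("AAAA"), 0)
  expect_equal(aromaticity("FFFF"), 1)
  # permutation invariance
  set.seed(2)
  p <- random_peptide(60L)
  q <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
  expect_equal(gravy(p), gravy(q))
  expect_equal(aromaticity(p), aromaticity(q))
})

test_that("isoelectric point solves the charge equation", {
  expect_equal(isoelectric_point("GG", tol = 1e-10), 5.525, tolerance = 1e-6)
  # adding an acidic residue lowers pI
  expect_lt(isoelectric_point("GGDGG"), isoelectric_point("GGGGG"))
  # net charge at the returned pI vanishes (independent charge oracle)
  set.seed(33)
  for (i in 1:50) {
    p <- random_peptide(50L)
    pI <- isoelectric_point(p)
    expect_lt(abs(oracle_net_charge(pI, p)), 1e-3)
  }
})

test_that("instability index follows the dipeptide weight formula", {
  # poly-A: every AA dipeptide weighs 1 -> II = 10 (L-1) / L
  expect_equal(instability_index("AAAAAA"), 10 * 5 / 6, tolerance = 1e-12)
  # length-2 peptide: II = 5 * DIWV(x1, x2); DIWV(A, C) = 44.94
  expect_equal(instability_index("AC"), 5 * 44.94, tolerance = 1e-12)
  # fixed 10-mer vs independent summation over the packaged table
  p <- "MKWVTFISLL"
  aa <- strsplit(p, "")[[1]]
  diwv <- ecosig:::.DIWV
  manual <- 10 / 10 * sum(vapply(1:9, function(i) diwv[aa[i], aa[i + 1]], 0))
  expect_equal(instability_index(p), manual, tolerance = 1e-12)
  # nonstandard residues take neutral weight 1
  expect_equal(instability_index("AXA"), 10 / 3 * 2, tolerance = 1e-12)
  # II is sensitive to residue order (unlike GRAVY)
  expect_false(isTRUE(all.equal(instability_index("ACDEFG"),
                                instability_index("GFEDCA"))))
})

test_that("the packaged dipeptide weight table is intact", {
  diwv <- ecosig:::.DIWV
  expect_equal(dim(diwv), c(20L, 20L))
  expect_equal(sum(diwv), 1831.841, tolerance = 1e-9)
  expect_equal(diwv["D", "P"], 1)
  expect_equal(diwv["G", "G"], 13.34)
})

test_that("secondary-structure fractions follow the smoothed propensity rule", {
  h <- ss_fractions(strrep("A", 30L))
  expect_gt(h[["helix"]], h[["sheet"]])
  cp <- ss_fractions(strrep("GP", 15L))
  expect_gt(cp[["coil"]], 50)
  expect_equal(sum(ss_fractions(random_peptide(40L))), 100, tolerance = 1e-9)
  # independent reimplementation of the stated rule on a fixed 30-mer
  p <- "MKWVTFISLLFLFSSAYSRGVFRRDAHKSE"
  aa <- strsplit(p, "")[[1]]
  ch <- ecosig:::.CF_HELIX[aa]; cs <- ecosig:::.CF_SHEET[aa]
  run_mean <- function(x, i) mean(x[max(1, i - 2):min(length(x), i + 2)])
  states <- vapply(seq_along(aa), function(i) {
    hh <- run_mean(ch, i); ss <- run_mean(cs, i)
    if (hh >= ss && hh > 1) "helix" else if (ss > hh && ss > 1) "sheet" else "coil"
  }, "")
  expect_equal(unname(ss_fractions(p)),
               unname(100 * c(mean(states == "helix"), mean(states == "sheet"),
                              mean(states == "coil"))), tolerance = 1e-12)
})

test_that("planted compositional shifts reproduce the ecotype trait ordering", {
  # HL-like proteomes: more aromatic residues, fewer hydrophobic ones
  ll_cfg <- simulation_config(seed = 71, genome_length = 50000L,
                              gene_count = 30L, gene_length_codons = 150L,
                              remnant_count = 0L)
  hl_cfg <- simulation_config(seed = 71, genome_length = 50000L,
                              gene_count = 30L, gene_length_codons = 150L,
                              remnant_count = 0L,
                              aa_shift = c(F = 1.8, Y = 1.8, W = 1.8,
                                           I = 0.6, V = 0.6, K = 1.4))
  prot_of <- function(cfg) {
    sim <- simulate_genome(cfg)
    extract_cds(sim$genome, sim$annotations, min_aa = 50L)$protein
  }
  ll <- protein_indices(prot_of(ll_cfg))
  hl <- protein_indices(prot_of(hl_cfg))
  expect_gt(mean(hl$aromaticity), mean(ll$aromaticity))
  expect_lt(mean(hl$gravy), mean(ll$gravy))
  expect_gt(mean(hl$pI), mean(ll$pI))
})
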