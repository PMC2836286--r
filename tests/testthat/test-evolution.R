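mk_hit <- function(q, s, pident, qlen, slen, evalue, bitscore = 100) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = qlen,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = qlen,
             sstart = 1L, send = slen, evalue = evalue, bitscore = bitscore,
             qlen = qlen, slen = slen, stringsAsFactors = FALSE)
}

test_that("ortholog screening applies identity, length and E-value thresholds", {
  h <- rbind(mk_hit("a", "b", 65, 300, 310, 1e-30),
             mk_hit("a", "c", 59.9, 300, 300, 1e-30),
             mk_hit("a", "d", 80, 200, 300, 1e-30),
             mk_hit("a", "e", 80, 300, 300, 1e-19))
  f <- filter_ortholog_hits(h)
  expect_equal(f$sseqid, "b")
  # boundary: exactly 60% identity and exactly 20% length difference pass
  h2 <- rbind(mk_hit("a", "b", 60, 240, 300, 1e-20))
  expect_equal(nrow(filter_ortholog_hits(h2)), 1L)
  expect_error(filter_ortholog_hits(h[, setdiff(names(h), "qlen")]), "qlen")
})

test_that("reciprocal best hits and clique cores behave on toy graphs", {
  gg <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C")
  both <- function(x, y) rbind(mk_hit(x, y, 90, 100, 100, 1e-50),
                               mk_hit(y, x, 90, 100, 100, 1e-50))
  # full triangle -> one core group
  h <- rbind(both("a1", "b1"), both("b1", "c1"), both("a1", "c1"))
  rbh <- filter_ortholog_hits(h, gg)
  core <- build_core_set(rbh, gg, c("A", "B", "C"))
  expect_equal(nrow(core), 1L)
  expect_equal(unname(unlist(core[1, c("A", "B", "C")])),
               c("a1", "b1", "c1"))
  # missing edge a1-c1 -> no core group under the clique rule
  h2 <- rbind(both("a1", "b1"), both("b1", "c1"))
  core2 <- build_core_set(filter_ortholog_hits(h2, gg), gg, c("A", "B", "C"))
  expect_equal(nrow(core2), 0L)
  # ...but single linkage accepts the chain
  core3 <- build_core_set(filter_ortholog_hits(h2, gg), gg, c("A", "B", "C"),
                          linkage = "single")
  expect_equal(nrow(core3), 1L)
  # RBH keeps only the mutual best when a stronger competing pair exists
  h3 <- rbind(both("a1", "b1"),
              mk_hit("a2", "b1", 95, 100, 100, 1e-80),
              mk_hit("b1", "a2", 95, 100, 100, 1e-80))
  rbh3 <- filter_ortholog_hits(h3, gg)
  expect_false(any(rbh3$qseqid == "a1" & rbh3$sseqid == "b1"))
  expect_true(any(rbh3$qseqid == "a2" & rbh3$sseqid == "b1"))
})

test_that("disrupted families drop out of the recovered core set", {
  set.seed(55)
  n_fam <- 25L; n_disrupt <- 5L
  genomes <- c("GA", "GB", "GC", "GD")
  proteins <- lapply(1:n_fam, function(i) random_peptide(150L))
  proteomes <- lapply(genomes, function(g) {
    ps <- vapply(proteins, function(p) {
      aa <- strsplit(p, "")[[1]]
      flip <- which(runif(150L) < 0.05)  # ~5% divergence between genomes
      aa[flip] <- vapply(flip, function(j) sample(setdiff(
        strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], aa[j]), 1L), "")
      paste(aa, collapse = "")
    }, "")
    setNames(ps, sprintf("%s_f%02d", g, 1:n_fam))
  })
  names(proteomes) <- genomes
  # disrupt the first n_disrupt families in genome GD (unrelated sequence)
  proteomes$GD[1:n_disrupt] <- vapply(1:n_disrupt,
                                      function(i) random_peptide(150L), "")
  hits <- make_hit_table(proteomes)
  gg <- unlist(lapply(genomes, function(g)
    setNames(rep(g, n_fam), names(proteomes[[g]]))))
  rbh <- filter_ortholog_hits(hits, gg)
  core <- build_core_set(rbh, gg, genomes)
  expect_equal(nrow(core), n_fam - n_disrupt)
  expect_false(any(grepl("f0[1-5]$", core$GA)))
})

test_that("codon alignment reproduces inputs and drops indel columns", {
  set.seed(12)
  a <- random_cds(40L)
  al <- codon_align_pair(a, a)
  expect_equal(al$a, al$b)
  expect_equal(paste(al$a, collapse = ""), a)
  # one internal codon insertion: that column is dropped, the rest align
  b <- paste0(substr(a, 1, 60), "GCT", substr(a, 61, nchar(a)))
  al2 <- codon_align_pair(a, b)
  expect_equal(length(al2$a), 40L)
  expect_equal(al2$a, al2$b)
  expect_error(codon_align_pair("ATGTAAAAA", "ATGTAAAAA"), "stop")
})

test_that("dN/dS site counts collapse to the unweighted method at R = 0.5", {
  # TTT: only TTC is synonymous (a transition) -> 1/3 syn site at R = 0.5
  aln <- list(a = c("TTT", "GGG"), b = c("TTT", "GGG"))
  e <- dnds_modified_ng(aln, R = 0.5)
  # GGG: all three third-position changes synonymous -> 1 site
  expect_equal(e$S, 1 / 3 + 1, tolerance = 1e-12)
  expect_equal(e$dN, 0)
  expect_equal(e$dS, 0)
})

test_that("dN/dS agrees with the exhaustive pathway oracle and is symmetric", {
  set.seed(91)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (rep in 1:25) {
    a <- sample(sense, 20L, replace = TRUE)
    b <- a
    # mutate one or two codons (avoiding stops)
    for (i in sample(20L, sample(1:2, 1L))) {
      repeat {
        cand <- strsplit(b[i], "")[[1]]
        p <- sample(3L, 1L)
        cand[p] <- sample(setdiff(c("A", "C", "G", "T"), cand[p]), 1L)
        cand <- paste(cand, collapse = "")
        if (Biostrings::GENETIC_CODE[[cand]] != "*") { b[i] <- cand; break }
      }
    }
    R <- sample(c(0.5, 1, 2, 4), 1L)
    e <- dnds_modified_ng(list(a = a, b = b), R = R)
    o <- oracle_dnds(a, b, R)
    expect_equal(e$S, o$S, tolerance = 1e-12)
    expect_equal(e$Sd, o$Sd, tolerance = 1e-12)
    expect_equal(e$Nd, o$Nd, tolerance = 1e-12)
    expect_equal(e$dS, o$dS, tolerance = 1e-12)
    expect_equal(e$dN, o$dN, tolerance = 1e-12)
    # symmetry
    e2 <- dnds_modified_ng(list(a = b, b = a), R = R)
    expect_identical(e$dN, e2$dN)
    expect_identical(e$dS, e2$dS)
  }
})

test_that("small-divergence estimates approach the uncorrected proportions", {
  set.seed(17)
  cds <- random_cds(300L)
  pr <- simulate_ortholog_pair(cds, t = 0.02, omega = 0.5, R = 2, seed = 5)
  aln <- list(a = split_codons(pr$a), b = split_codons(pr$b))
  e <- dnds_modified_ng(aln, R = 2)
  expect_equal(e$dS, e$Sd / e$S, tolerance = 0.03)
  expect_equal(e$dN, e$Nd / e$N, tolerance = 0.03)
})

test_that("positive-selection partitioning forms a proper Venn", {
  mk <- function(ids_pos, ids_all) data.frame(
    group_id = ids_all, dN = ifelse(ids_all %in% ids_pos, 0.2, 0.05),
    dS = 0.1, stringsAsFactors = FALSE)
  all_ids <- sprintf("OG%02d", 1:20)
  est <- list(p1 = mk(all_ids[1:5], all_ids),
              p2 = mk(all_ids[4:8], all_ids),
              p3 = mk(character(), all_ids))
  ps <- positive_selection_partition(est)
  expect_equal(unname(ps$per_pair), c(5L, 5L, 0L))
  expect_equal(unname(ps$venn[["p1_only"]]), 3L)
  expect_equal(unname(ps$venn[["p1&p2"]]), 2L)
  expect_equal(sum(ps$venn), length(union(ps$sets$p1, ps$sets$p2)))
  # all dN < dS -> empty everywhere
  none <- positive_selection_partition(list(a = mk(character(), all_ids),
                                            b = mk(character(), all_ids),
                                            c = mk(character(), all_ids)))
  expect_true(all(none$per_pair == 0))
  # NA estimates are excluded from the computable count
  est$p1$dS[1:3] <- NA
  ps2 <- positive_selection_partition(est)
  expect_equal(unname(ps2$computable[1L]), 17L)
})

test_that("synteny breakpoints count signed-adjacency violations", {
  n <- 8L
  coords <- function(ord, strands, L = 800L) {
    data.frame(gene_id = paste0("g", ord), start = (seq_along(ord) - 1L) * 100L,
               end = (seq_along(ord) - 1L) * 100L + 90L,
               strand = strands, stringsAsFactors = FALSE)
  }
  map0 <- structure(list(oriC = 0L, ter = 400L, genome_length = 800L),
                    class = "replichore_map")
  orth <- data.frame(gene_a = paste0("g", 1:n), gene_b = paste0("g", 1:n),
                     stringsAsFactors = FALSE)
  # identical order and strands: no breakpoints, all same-strand
  ca <- coords(1:n, rep("+", n))
  sc <- synteny_compare(orth, ca, ca, map0, map0)
  expect_equal(sc$breakpoints, 0L)
  expect_true(all(sc$pairs$same_strand))
  # single inverted block of 3 genes: 2 breakpoints, 3 opposite-strand pairs
  ord_b <- c(1L, 4L, 3L, 2L, 5L, 6L, 7L, 8L)
  str_b <- rep("+", n); str_b[2:4] <- "-"
  cb <- coords(1:n, rep("+", n))
  cb$gene_id <- paste0("g", ord_b)
  cb$strand <- str_b
  sc2 <- synteny_compare(orth, ca, cb, map0, map0)
  expect_equal(sc2$breakpoints, 2L)
  expect_equal(sum(!sc2$pairs$same_strand), 3L)
  # random permutations give close to n - 1 breakpoints
  set.seed(44)
  n2 <- 60L
  orth2 <- data.frame(gene_a = paste0("g", 1:n2), gene_b = paste0("g", 1:n2),
                      stringsAsFactors = FALSE)
  ca2 <- data.frame(gene_id = paste0("g", 1:n2),
                    start = (0:(n2 - 1)) * 100L, end = (0:(n2 - 1)) * 100L + 90L,
                    strand = "+", stringsAsFactors = FALSE)
  map2 <- structure(list(oriC = 0L, ter = 3000L, genome_length = 6000L),
                    class = "replichore_map")
  bps <- replicate(5, {
    cb2 <- ca2
    cb2$gene_id <- paste0("g", sample(n2))
    synteny_compare(orth2, ca2, cb2, map2, map2)$breakpoints
  })
  expect_true(all(bps > 0.8 * (n2 - 1)))
})

test_that("remnant screening applies thresholds and summarizes merged regions", {
  g <- genome_record("R", paste0(strrep("AT", 250L), strrep("GC", 250L)),
                     "linear")
  segments <- data.frame(segment_id = c("s1", "s2"), start = c(0L, 500L),
                         end = c(500L, 1000L), length = 500L, gc = c(0, 1),
                         stringsAsFactors = FALSE)
  hits <- data.frame(
    qseqid = c("s1", "s1", "s2", "s2", "s2"),
    sseqid = paste0("gene", 1:5),
    pident = c(45, 29, 80, 35, 90),
    length = c(20L, 50L, 14L, 30L, 40L),
    evalue = c(1e-5, 1e-9, 1e-9, 5e-3, 1e-8),
    qstart = c(10L, 100L, 1L, 1L, 200L),
    qend = c(70L, 160L, 42L, 90L, 320L), stringsAsFactors = FALSE)
  fr <- filter_remnant_hits(hits, segments, g)
  # pass: row 1 (s1) and row 5 (s2); fail: identity 29, length 14, E 5e-3
  expect_equal(fr$summary$n_hits, 2L)
  expect_equal(sort(fr$remnants$segment_id), c("s1", "s2"))
  gcs <- sort(fr$remnants$gc_pct)
  expect_equal(gcs, c(0, 100))
  expect_equal(fr$summary$mean_gc_pct, 50)
  expect_equal(fr$summary$sd_gc_pct, stats::sd(c(0, 100)))
  # overlapping passing hits merge into one region
  hits2 <- rbind(hits[1, ], within(hits[1, ], { qstart <- 40L; qend <- 120L }))
  fr2 <- filter_remnant_hits(hits2, segments, g)
  expect_equal(fr2$summary$n_hits, 1L)
  expect_equal(fr2$remnants$end - fr2$remnants$start, 111L)
})
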