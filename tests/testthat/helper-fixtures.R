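# Shared fixtures and independent oracles for the test suite.

BASES <- c("A", "C", "G", "T")
GC_TAB <- Biostrings::GENETIC_CODE

split_codons <- function(s) {
  n <- nchar(s)
  substring(s, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random in-frame stop-free CDS of n codons (incl. ATG start, no stop)
random_cds <- function(n_codons) {
  sense <- names(GC_TAB)[GC_TAB != "*"]
  paste(c("ATG", sample(sense, n_codons - 1L, replace = TRUE)), collapse = "")
}

random_peptide <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

write_genbank_fixture <- function(path, sequence, features,
                                  topology = "circular") {
  # features: data.frame(key, location, locus_tag)
  lines <- c(sprintf(
    "LOCUS       TESTREC     %d bp    DNA     %s BCT 01-JAN-2000",
    nchar(sequence), topology),
    "DEFINITION  Synthetic fixture.",
    "ACCESSION   TESTREC", "VERSION     TESTREC.1",
    "FEATURES             Location/Qualifiers")
  for (i in seq_len(nrow(features))) {
    lines <- c(lines,
               sprintf("     %-15s %s", features$key[i], features$location[i]),
               sprintf("                     /locus_tag=\"%s\"",
                       features$locus_tag[i]))
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(sequence)
  pos <- 1L
  while (pos <= nchar(s)) {
    chunk <- substr(s, pos, min(pos + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", pos, paste(blocks, collapse = " ")))
    pos <- pos + 60L
  }
  writeLines(c(lines, "//"), path)
  path
}

# ---- independent modified Nei-Gojobori oracle --------------------------
# Recomputes S/N site counts, exhaustive pathway-averaged Sd/Nd and the
# Jukes-Cantor correction from first principles, sharing no code with the
# package implementation.

oracle_syn_fraction <- function(codon, R) {
  b <- strsplit(codon, "")[[1]]
  aa <- GC_TAB[[codon]]
  s <- 0
  for (p in 1:3) {
    others <- setdiff(BASES, b[p])
    for (nb in others) {
      transition <- (b[p] %in% c("A", "G") && nb %in% c("A", "G")) ||
        (b[p] %in% c("C", "T") && nb %in% c("C", "T"))
      w <- if (transition) R / (R + 1) else 1 / (2 * (R + 1))
      m <- b; m[p] <- nb
      if (GC_TAB[[paste(m, collapse = "")]] == aa) s <- s + w
    }
  }
  s
}

oracle_pathways <- function(ca, cb) {
  ba <- strsplit(ca, "")[[1]]
  bb <- strsplit(cb, "")[[1]]
  d <- which(ba != bb)
  if (length(d) == 0L) return(c(0, 0))
  orders <- if (length(d) == 1L) list(d) else {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
      out
    }
    perms(d)
  }
  acc <- list()
  for (ord in orders) {
    cur <- ba
    sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- bb[p]
      a1 <- GC_TAB[[paste(cur, collapse = "")]]
      a2 <- GC_TAB[[paste(nxt, collapse = "")]]
      if (a1 == "*" || a2 == "*") { ok <- FALSE; break }
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) acc[[length(acc) + 1L]] <- c(sd, nd)
  }
  if (length(acc) == 0L) return(NULL)  # caller decides the fallback
  colMeans(do.call(rbind, acc))
}

oracle_dnds <- function(codons_a, codons_b, R) {
  S <- (sum(vapply(codons_a, oracle_syn_fraction, 0, R = R)) +
          sum(vapply(codons_b, oracle_syn_fraction, 0, R = R))) / 2
  N <- 3 * length(codons_a) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(codons_a)) {
    pw <- oracle_pathways(codons_a[i], codons_b[i])
    if (is.null(pw)) stop("oracle: all pathways blocked (not used in tests)")
    Sd <- Sd + pw[1]; Nd <- Nd + pw[2]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, dS = jc(Sd / S), dN = jc(Nd / N))
}

# net-charge oracle for the isoelectric point (Bjellqvist set, independent
# arithmetic)
oracle_net_charge <- function(pH, peptide) {
  aa <- strsplit(peptide, "")[[1]]
  nterm <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
             E = 7.70)[aa[1]]
  if (is.na(nterm)) nterm <- 7.5
  pos <- c(nterm, c(H = 5.98, K = 10, R = 12)[aa[aa %in% c("H", "K", "R")]])
  neg <- c(3.55, c(C = 9, D = 4.05, E = 4.45, Y = 10)[aa[aa %in% c("C", "D", "E", "Y")]])
  sum(10^pos / (10^pos + 10^pH)) - sum(10^pH / (10^pH + 10^neg))
}
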