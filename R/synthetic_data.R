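# Seeded synthetic-genome generator. Every signal the pipeline measures is
# planted with known parameters (origin position, leading-strand G+T excess,
# codon-usage dispersion, intergenic A+T enrichment, decayed gene remnants,
# per-family divergence), so each analysis stage has a recovery-testable
# input that needs no downloads.

#' Simulation configuration
#'
#' Assembles and validates the parameter set for
#' \code{\link{simulate_genome}}. Defaults describe a reduced, A+T-rich
#' marine picocyanobacterium-like replicon at desk scale: a 200 kb circular
#' chromosome with 150 genes (mean 300 codons), genomic G+C 35\%,
#' intergenic spacers 5 points more A+T-rich than the genome, a
#' leading-strand G+T excess of 0.10, and ten decayed gene remnants.
#'
#' @param seed integer seed; mandatory — the generator has no unseeded
#'   randomness.
#' @param id genome identifier.
#' @param genome_length replicon length (nt).
#' @param topology \code{"circular"} or \code{"linear"}.
#' @param oriC,ter origin/terminus positions; \code{NULL} draws oriC
#'   uniformly and places ter diametrically opposite.
#' @param delta leading-strand G+T excess: probability that a synonymous
#'   third position of a leading-strand gene is switched to a G/T-ending
#'   codon, and the intergenic purine/keto skew on the leading strand.
#' @param gene_count number of protein-coding genes.
#' @param gene_length_codons mean gene length in codons (including start
#'   and stop); lengths are drawn around it.
#' @param gc genomic target G+C fraction of coding codon sampling.
#' @param intergenic_gc_offset added to \code{gc} for spacers (negative =
#'   A+T-enriched intergenic DNA).
#' @param concentration Dirichlet concentration of per-gene codon usage
#'   around the composition prior (larger = more homogeneous genes).
#' @param aa_shift named multipliers on amino-acid weights (e.g.
#'   \code{c(T = 0.5)} depletes Thr codons).
#' @param cg_depletion in [0, 1]: down-weighting of CpG in codon choice and
#'   spacer composition (0 = off).
#' @param remnant_count number of decayed gene copies inserted into
#'   spacers.
#' @param remnant_decay per-base substitution probability of remnant decay.
#' @param remnant_at_bias probability that a decay substitution is to A or
#'   T (A+T-biased mutational spectrum).
#' @param trna_count small structural-RNA genes added (exercise intergenic
#'   subtraction).
#' @param ancestor_cds optional named character vector of ancestral CDS
#'   (start/stop included): the genome's genes are then diverged copies of
#'   these (orthologous families across genomes sharing the ancestor)
#'   instead of freshly sampled; overrides \code{gene_count}.
#' @param divergence_t,divergence_omega,divergence_R branch length
#'   (expected substitutions per codon from the ancestor = t/2), planted
#'   dN/dS and ts/tv ratio of the divergence process (ancestor mode only).
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(seed,
                              id = "SYN",
                              genome_length = 200000L,
                              topology = "circular",
                              oriC = NULL, ter = NULL,
                              delta = 0.10,
                              gene_count = 150L,
                              gene_length_codons = 300L,
                              gc = 0.35,
                              intergenic_gc_offset = -0.05,
                              concentration = 40,
                              aa_shift = NULL,
                              cg_depletion = 0,
                              remnant_count = 10L,
                              remnant_decay = 0.10,
                              remnant_at_bias = 0.75,
                              trna_count = 2L,
                              ancestor_cds = NULL,
                              divergence_t = 0.2,
                              divergence_omega = 0.3,
                              divergence_R = 2) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(delta >= 0, delta <= 1, gc > 0, gc < 1,
            cg_depletion >= 0, cg_depletion <= 1,
            remnant_decay >= 0, remnant_decay <= 1,
            remnant_at_bias >= 0, remnant_at_bias <= 1)
  if (!is.null(oriC) && !is.null(ter) && oriC == ter)
    stop("oriC and ter must differ")
  structure(as.list(environment()), class = "simulation_config")
}

.rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

# composition prior over the 61 sense codons given a target G+C (and
# optional amino-acid weighting / CpG depletion)
.codon_prior <- function(gc, aa_shift = NULL, cg_depletion = 0) {
  pb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  w <- vapply(.SENSE_CODONS, function(cod) {
    b <- strsplit(cod, "")[[1]]
    prod(pb[b])
  }, 0)
  if (!is.null(aa_shift)) {
    aa <- .GENETIC_CODE[.SENSE_CODONS]
    for (nm in names(aa_shift)) w[aa == nm] <- w[aa == nm] * aa_shift[[nm]]
  }
  if (cg_depletion > 0) {
    ncg <- vapply(.SENSE_CODONS, function(cod)
      lengths(regmatches(cod, gregexpr("CG", cod))), 0L)
    w <- w * (1 - cg_depletion)^ncg
  }
  w / sum(w)
}

# switch a codon, with probability delta, to a synonymous same-stem codon
# whose third position is in `toward` (keto G/T for leading-strand genes,
# amino A/C for lagging-strand genes: the two coding strands experience
# complementary mutational pressure)
.enrich_third <- function(codons, delta, toward) {
  if (delta <= 0) return(codons)
  n <- length(codons)
  do_it <- stats::runif(n) < delta
  for (i in which(do_it)) {
    cod <- codons[i]
    stem <- substr(cod, 1L, 2L)
    alts <- paste0(stem, toward)
    alts <- alts[alts %in% .SENSE_CODONS &
                   .GENETIC_CODE[alts] == .GENETIC_CODE[[cod]]]
    if (length(alts)) codons[i] <- sample(alts, 1L)
  }
  codons
}

# intergenic base sampling with leading-strand keto (G+T) excess
.spacer_probs <- function(gc, delta, leading_plus) {
  s <- if (leading_plus) delta else -delta
  p <- c(A = (1 - gc) / 2 * (1 - s), C = gc / 2 * (1 - s),
         G = gc / 2 * (1 + s), T = (1 - gc) / 2 * (1 + s))
  p / sum(p)
}

.sample_bases <- function(n, probs, cg_depletion = 0) {
  if (n <= 0L) return("")
  b <- sample(names(probs), n, replace = TRUE, prob = probs)
  if (cg_depletion > 0 && n >= 2L) {
    is_cg <- which(b[-n] == "C" & b[-1L] == "G")
    fix <- is_cg[stats::runif(length(is_cg)) < cg_depletion]
    b[fix + 1L] <- "A"
  }
  paste(b, collapse = "")
}

# mutate a sequence at rate mu with an A+T-biased substitution spectrum
.decay_sequence <- function(s, mu, at_bias) {
  b <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(b)) < mu)
  for (i in hit) {
    pool <- setdiff(.BASES, b[i])
    wts <- ifelse(pool %in% c("A", "T"), at_bias / 2, (1 - at_bias) / 2)
    b[i] <- sample(pool, 1L, prob = wts)
  }
  paste(b, collapse = "")
}

#' Simulate a genome with planted signals
#'
#' Builds a circular (or linear) replicon: protein-coding genes placed
#' alternately on the two strands separated by A+T-enriched spacers, codon
#' usage drawn per gene from a Dirichlet around a G+C-target prior,
#' synonymous third positions of leading-strand genes enriched toward G/T
#' with probability \code{delta} (and spacers skewed the same way), decayed
#' copies of randomly chosen genes inserted into spacers as remnants, and a
#' couple of structural-RNA genes. All planted quantities are returned in
#' the truth object.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{genome} (a \code{genome_record}),
#'   \code{annotations} (a \code{gene_annotation}) and \code{truth} (list:
#'   \code{oriC}, \code{ter}, \code{genes} with planted strand classes,
#'   \code{remnants} with coordinates and source genes, \code{config}).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- as.integer(config$genome_length)
  oriC <- config$oriC %||% (sample.int(L, 1L) - 1L)
  ter <- config$ter %||% ((oriC + L %/% 2L) %% L)
  ancestor <- config$ancestor_cds
  if (is.null(ancestor)) {
    ng <- config$gene_count
    len_codons <- pmax(60L, as.integer(round(stats::rnorm(
      ng, config$gene_length_codons, config$gene_length_codons / 5))))
    div_rates <- NULL
  } else {
    ng <- length(ancestor)
    len_codons <- as.integer(nchar(ancestor) / 3L)
    div_rates <- .codon_mutation_rates(config$divergence_R,
                                       config$divergence_omega)
  }
  gene_nt <- 3L * len_codons
  # structural RNAs (fixed 75 nt)
  ntr <- config$trna_count
  trna_nt <- rep(75L, ntr)
  # remnant sources chosen among genes; remnant length = source CDS length
  nrem <- min(config$remnant_count, ng)
  rem_src <- if (nrem > 0L) sort(sample.int(ng, nrem)) else integer()
  rem_nt <- gene_nt[rem_src]
  total_fixed <- sum(gene_nt) + sum(trna_nt) + sum(rem_nt)
  n_units <- ng + ntr
  spacer_total <- L - total_fixed
  if (spacer_total < n_units)
    stop("infeasible packing: genes, RNAs and remnants exceed genome length")
  gaps <- as.vector(stats::rmultinom(1L, spacer_total - n_units,
                                     rep(1, n_units))) + 1L
  # interleave tRNAs at random unit slots
  unit_kind <- sample(c(rep("CDS", ng), rep("tRNA", ntr)))
  rem_gap <- if (nrem > 0L) sample(n_units, nrem) else integer()
  rem_of_gap <- stats::setNames(rep(NA_integer_, n_units), NULL)
  rem_of_gap[rem_gap] <- seq_len(nrem)

  arc1 <- function(pos) {
    d_ori <- (pos - oriC) %% L
    d_ter <- (ter - oriC) %% L
    d_ori > 0 & d_ori <= d_ter
  }
  prior <- .codon_prior(config$gc, config$aa_shift, config$cg_depletion)
  alpha <- config$concentration * length(prior) * prior

  pieces <- character(0)
  pos <- 0L
  genes <- list()
  rnas <- list()
  remnants <- list()
  gene_seqs <- character(ng)  # coding-strand CDS incl. start/stop
  gi <- 0L; ti <- 0L
  for (u in seq_len(n_units)) {
    # spacer (possibly hosting a remnant); skew sign from current midpoint
    gap_len <- gaps[u]
    mid_gap <- (pos + gap_len / 2) %% L
    lead_plus <- arc1(mid_gap)
    sp_gc <- max(0.02, min(0.98, config$gc + config$intergenic_gc_offset))
    pr <- .spacer_probs(sp_gc, config$delta, lead_plus)
    if (!is.na(rem_of_gap[u])) {
      ri <- rem_of_gap[u]
      left <- gap_len %/% 2L
      right <- gap_len - left
      src <- rem_src[ri]
      # decayed copy of the source gene's coding-strand sequence (the
      # source CDS is generated later for low unit indices; generate the
      # remnant from the same codon model instead when not yet available)
      rem_seq_placeholder <- NA_character_
      pieces <- c(pieces, .sample_bases(left, pr, config$cg_depletion))
      rem_start <- pos + left
      pieces <- c(pieces, strrep("N", 0))  # placeholder slot, filled below
      rem_slot <- length(pieces)
      rem_end <- rem_start + rem_nt[ri]
      pieces <- c(pieces, .sample_bases(right, pr, config$cg_depletion))
      remnants[[ri]] <- list(slot = rem_slot, start = rem_start,
                             end = rem_end, source_idx = src)
      pos <- pos + gap_len + rem_nt[ri]
    } else {
      pieces <- c(pieces, .sample_bases(gap_len, pr, config$cg_depletion))
      pos <- pos + gap_len
    }
    if (unit_kind[u] == "tRNA") {
      ti <- ti + 1L
      t_seq <- .sample_bases(trna_nt[ti], .spacer_probs(config$gc, 0, TRUE))
      pieces <- c(pieces, t_seq)
      rnas[[ti]] <- data.frame(gene_id = sprintf("%s_t%02d", config$id, ti),
                               start = pos, end = pos + trna_nt[ti],
                               strand = if (ti %% 2L == 0L) "-" else "+",
                               kind = "tRNA", translation = NA_character_,
                               stringsAsFactors = FALSE)
      pos <- pos + trna_nt[ti]
      next
    }
    gi <- gi + 1L
    strand <- if (gi %% 2L == 1L) "+" else "-"
    start <- pos
    end <- pos + gene_nt[gi]
    mid <- ((start + end) / 2) %% L
    leading <- (strand == "+") == arc1(mid)
    # sample (or inherit and diverge) the coding-strand codons
    n_mid <- len_codons[gi] - 2L
    if (is.null(ancestor)) {
      q <- .rdirichlet1(alpha)
      mids <- sample(.SENSE_CODONS, n_mid, replace = TRUE, prob = q)
    } else {
      anc <- ancestor[[gi]]
      anc_codons <- substring(anc, seq(1L, nchar(anc) - 2L, 3L),
                              seq(3L, nchar(anc), 3L))
      mids <- .evolve_codons(anc_codons[seq(2L, length(anc_codons) - 1L)],
                             config$divergence_t / 2, div_rates)
    }
    mids <- .enrich_third(mids, config$delta,
                          if (leading) c("G", "T") else c("A", "C"))
    cds <- c("ATG", mids, "TAA")
    cds_str <- paste(cds, collapse = "")
    gene_seqs[gi] <- cds_str
    pieces <- c(pieces, if (strand == "+") cds_str else revcomp(cds_str))
    genes[[gi]] <- data.frame(
      gene_id = sprintf("%s_g%04d", config$id, gi),
      start = start, end = end, strand = strand, kind = "CDS",
      translation = NA_character_,
      replichore = if (arc1(mid)) 1L else 2L,
      strand_class = if (leading) "leading" else "lagging",
      stringsAsFactors = FALSE)
    pos <- pos + gene_nt[gi]
  }
  # fill remnant slots now that all source CDS exist
  for (ri in seq_along(remnants)) {
    r <- remnants[[ri]]
    decayed <- .decay_sequence(gene_seqs[r$source_idx],
                               config$remnant_decay, config$remnant_at_bias)
    pieces[r$slot] <- decayed
  }
  sequence <- paste(pieces, collapse = "")
  stopifnot(nchar(sequence) == L)
  genome <- genome_record(config$id, sequence, config$topology)
  gdf <- do.call(rbind, genes)
  adf <- rbind(gdf[, c("gene_id", "start", "end", "strand", "kind",
                       "translation")],
               if (ti > 0L) do.call(rbind, rnas))
  adf <- adf[order(adf$start), , drop = FALSE]
  rownames(adf) <- NULL
  class(adf) <- c("gene_annotation", "data.frame")
  truth <- list(
    oriC = oriC, ter = ter,
    genes = gdf[, c("gene_id", "start", "end", "strand", "replichore",
                    "strand_class")],
    remnants = if (length(remnants)) data.frame(
      start = vapply(remnants, `[[`, 0, "start"),
      end = vapply(remnants, `[[`, 0, "end"),
      source_gene = gdf$gene_id[vapply(remnants, `[[`, 0L, "source_idx")],
      stringsAsFactors = FALSE) else data.frame(),
    cds = stats::setNames(gene_seqs, gdf$gene_id),
    config = config)
  list(genome = genome, annotations = adf, truth = truth)
}

# per-codon accepted mutation table under the simulator's model
.codon_mutation_rates <- function(R, omega) {
  lapply(stats::setNames(nm = .SENSE_CODONS), function(cod) {
    b <- strsplit(cod, "")[[1]]
    tgt <- character(); rate <- numeric()
    for (pos in 1:3) {
      for (nb in setdiff(.BASES, b[pos])) {
        mut <- b; mut[pos] <- nb
        mcod <- paste(mut, collapse = "")
        base_rate <- (1 / 3) * if (.is_transition(b[pos], nb))
          R / (R + 1) else 1 / (2 * (R + 1))
        aa1 <- .GENETIC_CODE[[cod]]; aa2 <- .GENETIC_CODE[[mcod]]
        acc <- if (aa2 == "*") 0 else if (aa1 == aa2) 1 else omega
        if (acc > 0) { tgt <- c(tgt, mcod); rate <- c(rate, base_rate * acc) }
      }
    }
    list(target = tgt, rate = rate, total = sum(rate))
  })
}

# evolve a codon vector for `time` units by a Gillespie walk
.evolve_codons <- function(codons, time, rates) {
  lam <- vapply(codons, function(c) rates[[c]]$total, 0)
  t_now <- 0
  repeat {
    Lam <- sum(lam)
    if (Lam <= 0) break
    t_now <- t_now + stats::rexp(1L, Lam)
    if (t_now > time) break
    i <- sample.int(length(codons), 1L, prob = lam)
    r <- rates[[codons[i]]]
    j <- if (length(r$rate) == 1L) 1L else
      sample.int(length(r$rate), 1L, prob = r$rate)
    codons[i] <- r$target[j]
    lam[i] <- rates[[codons[i]]]$total
  }
  codons
}

#' Simulate a diverged ortholog pair at controlled omega
#'
#' Continuous-time codon substitution along the two branches of a pair:
#' per-site mutations with transition/transversion ratio R, nonsynonymous
#' changes accepted with relative rate omega, stop-creating mutations
#' rejected. Each copy evolves for t/2, so the pair separates by an
#' expected total of about t accepted substitutions per codon at
#' omega = 1.
#'
#' @param cds stop-free in-frame coding sequence (ancestor).
#' @param t total divergence time (expected substitutions per codon between
#'   the pair, before selective removal of nonsynonymous changes).
#' @param omega relative acceptance rate of nonsynonymous changes
#'   (dN/dS planted).
#' @param R transition/transversion ratio of the mutation process.
#' @param seed integer seed.
#' @return list with diverged sequences \code{a} and \code{b} and the
#'   planted parameters.
#' @export
simulate_ortholog_pair <- function(cds, t, omega, R = 2, seed) {
  if (omega < 0) stop("omega must be non-negative")
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  codons <- substring(cds, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  if (any(codons %in% .STOP_CODONS)) stop("CDS contains a stop codon")
  rates <- .codon_mutation_rates(R, omega)
  a <- .evolve_codons(codons, t / 2, rates)
  b <- .evolve_codons(codons, t / 2, rates)
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""),
       t = t, omega = omega, R = R)
}

#' Simulate a panel of related genomes
#'
#' Generates an ancestral genome, then derives each panel member by
#' diverging every ancestral gene along its own branch (planted dN/dS and
#' ts/tv ratio) and re-assembling a genome with its own origin placement,
#' leading-strand bias and spacers. Genes with the same family index are
#' orthologs across the panel, so ortholog recovery, core-set
#' construction, dN/dS and synteny all have generator truth.
#'
#' @param base_config \code{\link{simulation_config}} for the ancestor
#'   (its \code{divergence_*} fields set the per-branch process).
#' @param ids character vector of genome identifiers (one per member).
#' @param deltas per-member leading-strand G+T excess (recycled).
#' @param seed integer seed; member g uses \code{seed + g}.
#' @return list with \code{panels} (list of simulate_genome outputs, named
#'   by id), \code{ancestor} and \code{families} (data.frame: family,
#'   one gene-id column per genome).
#' @export
simulate_panel <- function(base_config, ids, deltas = 0.1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  deltas <- rep_len(deltas, length(ids))
  anc_cfg <- base_config
  anc_cfg$seed <- seed
  ancestor <- simulate_genome(anc_cfg)
  panels <- list()
  for (g in seq_along(ids)) {
    cfg <- base_config
    cfg$seed <- seed + g
    cfg$id <- ids[g]
    cfg$delta <- deltas[g]
    cfg$oriC <- NULL; cfg$ter <- NULL
    cfg$ancestor_cds <- ancestor$truth$cds
    panels[[ids[g]]] <- simulate_genome(cfg)
  }
  fam_idx <- sprintf("g%04d", seq_along(ancestor$truth$cds))
  families <- data.frame(family = fam_idx, stringsAsFactors = FALSE)
  for (g in ids) families[[g]] <- sprintf("%s_%s", g, fam_idx)
  list(panels = panels, ancestor = ancestor, families = families)
}

# unique k-mers of a string
.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, 1:(n - k + 1L), k:n))
}

# candidate pairs of ids sharing at least min_shared k-mers
.kmer_candidates <- function(seqs_a, seqs_b, k, min_shared) {
  ka <- lapply(seqs_a, .kmers, k = k)
  kb <- lapply(seqs_b, .kmers, k = k)
  dfa <- data.frame(kmer = unlist(ka),
                    a = rep(names(seqs_a), lengths(ka)),
                    stringsAsFactors = FALSE)
  dfb <- data.frame(kmer = unlist(kb),
                    b = rep(names(seqs_b), lengths(kb)),
                    stringsAsFactors = FALSE)
  m <- merge(dfa, dfb, by = "kmer")
  if (nrow(m) == 0L) return(data.frame(a = character(), b = character()))
  tab <- stats::aggregate(kmer ~ a + b, data = m, FUN = length)
  tab[tab$kmer >= min_shared, c("a", "b"), drop = FALSE]
}

#' Build a tabular hit file from simulated proteomes
#'
#' All-against-all pairwise global protein alignments between genomes
#' (Needleman-Wunsch, BLOSUM62; a shared-k-mer prefilter skips hopeless
#' pairs), written as rows of the standard 12-column tabular dialect plus
#' qlen/slen. The E-value surrogate is deterministic and monotone in the
#' alignment score: E = qlen * slen * 2^(-score/2), so threshold logic is
#' exercised exactly; it is not a Karlin-Altschul E-value.
#'
#' @param proteomes named list (genome id -> named character vector of
#'   proteins).
#' @param kmer_k,kmer_min prefilter parameters (default: pairs sharing at
#'   least 4 distinct 5-mers are aligned).
#' @return hit data.frame in \code{\link{read_hit_table}} column layout
#'   (both orientations of each aligned pair).
#' @export
make_hit_table <- function(proteomes, kmer_k = 5L, kmer_min = 4L) {
  gids <- names(proteomes)
  stopifnot(!is.null(gids), all(vapply(proteomes, function(p)
    !is.null(names(p)), TRUE)))
  rows <- list()
  for (i in seq_along(gids)) for (j in seq_along(gids)) {
    if (i >= j) next
    pa <- proteomes[[i]]; pb <- proteomes[[j]]
    cand <- .kmer_candidates(pa, pb, kmer_k, kmer_min)
    for (r in seq_len(nrow(cand))) {
      qa <- cand$a[r]; qb <- cand$b[r]
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(pa[[qa]]), Biostrings::AAString(pb[[qb]]),
        substitutionMatrix = "BLOSUM62", gapOpening = 10,
        gapExtension = 0.5, type = "global")
      alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
      ident <- Biostrings::nmatch(aln)
      pid <- 100 * ident / alen
      score <- Biostrings::score(aln)
      qlen <- nchar(pa[[qa]]); slen <- nchar(pb[[qb]])
      ev <- qlen * slen * 2^(-score / 2)
      gapopen <- sum(unlist(Biostrings::nindel(aln)@insertion[, 1L]),
                     unlist(Biostrings::nindel(aln)@deletion[, 1L]))
      mism <- alen - ident -
        (sum(Biostrings::nindel(aln)@insertion[, 2L]) +
           sum(Biostrings::nindel(aln)@deletion[, 2L]))
      mk <- function(q, s, ql, sl) data.frame(
        qseqid = q, sseqid = s, pident = pid, length = alen,
        mismatch = mism, gapopen = gapopen, qstart = 1L, qend = ql,
        sstart = 1L, send = sl, evalue = ev, bitscore = score,
        qlen = ql, slen = sl, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- mk(qa, qb, qlen, slen)
      rows[[length(rows) + 1L]] <- mk(qb, qa, slen, qlen)
    }
  }
  if (length(rows) == 0L)
    return(stats::setNames(as.data.frame(
      rep(list(character()), length(.HIT_COLS))), .HIT_COLS))
  do.call(rbind, rows)
}

#' Naive translated search of intergenic segments against a gene pool
#'
#' Test-scale stand-in for an external six-frame translated search: for
#' each (segment, gene) pair passing a shared nucleotide k-mer prefilter,
#' all six reading frames of the segment are locally aligned (Smith-
#' Waterman, BLOSUM62) against the gene's protein, and the best frame is
#' reported as a tabular hit with segment-relative nucleotide coordinates.
#' Uses the same deterministic E-value surrogate as
#' \code{\link{make_hit_table}}.
#'
#' @param segments intergenic segment table from
#'   \code{\link{extract_intergenic}}.
#' @param genome the corresponding \code{genome_record}.
#' @param proteins named character vector of gene proteins.
#' @param kmer_k,kmer_min peptide prefilter: only (segment, gene) pairs
#'   sharing at least \code{kmer_min} distinct peptide \code{kmer_k}-mers
#'   are aligned (defaults 5, 5).
#' @return hit data.frame with columns \code{qseqid, sseqid, pident,
#'   length, evalue, qstart, qend} (nt, 1-based within the segment).
#' @export
naive_translated_search <- function(segments, genome, proteins,
                                    kmer_k = 5L, kmer_min = 5L) {
  seg_seqs <- stats::setNames(
    vapply(seq_len(nrow(segments)), function(i)
      slice_genome(genome, segments$start[i], segments$end[i]), ""),
    segments$segment_id)
  # nucleotide prefilter against back-translated... simpler: against CDS is
  # not available here, so prefilter on shared peptide 4-mers of the six
  # frames instead when segments are short; nucleotide prefilter needs the
  # gene CDS, so translate frames and use peptide k-mers.
  frame_translations <- lapply(seg_seqs, function(s) {
    fr <- list()
    for (strand in c("+", "-")) {
      ss <- if (strand == "+") s else revcomp(s)
      for (off in 0:2) {
        sub <- substr(ss, off + 1L, off + 3L * ((nchar(ss) - off) %/% 3L))
        if (nchar(sub) >= 3L)
          fr[[paste0(strand, off)]] <- suppressWarnings(translate_cds(sub))
      }
    }
    fr
  })
  prot_kmers <- lapply(proteins, .kmers, k = kmer_k)
  rows <- list()
  for (seg_id in names(seg_seqs)) {
    frames <- frame_translations[[seg_id]]
    if (length(frames) == 0L) next
    # peptide k-mer prefilter over stop-split fragments
    seg_pep <- unlist(lapply(frames, function(p) strsplit(p, "\\*")[[1]]))
    seg_pep <- seg_pep[nchar(seg_pep) >= 8L]
    if (length(seg_pep) == 0L) next
    seg_kmers <- unique(unlist(lapply(seg_pep, .kmers, k = kmer_k)))
    for (g in names(proteins)) {
      shared <- sum(prot_kmers[[g]] %in% seg_kmers)
      if (shared < kmer_min) next
      best <- NULL
      for (fname in names(frames)) {
        pep <- chartr("*", "X", frames[[fname]])
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(pep), Biostrings::AAString(proteins[[g]]),
          substitutionMatrix = "BLOSUM62", gapOpening = 10,
          gapExtension = 0.5, type = "local")
        if (is.null(best) || Biostrings::score(aln) > best$score)
          best <- list(aln = aln, frame = fname, score = Biostrings::score(aln))
      }
      aln <- best$aln
      alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
      if (alen == 0L) next
      ident <- Biostrings::nmatch(aln)
      pid <- 100 * ident / alen
      seg_len <- nchar(seg_seqs[[seg_id]])
      ev <- seg_len * nchar(proteins[[g]]) * 2^(-best$score / 2)
      # aa range within the frame -> nt range within the segment
      aa_s <- Biostrings::start(Biostrings::pattern(aln))
      aa_e <- Biostrings::end(Biostrings::pattern(aln))
      strand <- substr(best$frame, 1L, 1L)
      off <- as.integer(substr(best$frame, 2L, 2L))
      nt_s <- off + 3L * (aa_s - 1L) + 1L
      nt_e <- off + 3L * aa_e
      if (strand == "-") {
        tmp <- nt_s
        nt_s <- seg_len - nt_e + 1L
        nt_e <- seg_len - tmp + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        qseqid = seg_id, sseqid = g, pident = pid, length = alen,
        evalue = ev, qstart = nt_s, qend = nt_e, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(),
                      evalue = numeric(), qstart = integer(),
                      qend = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
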