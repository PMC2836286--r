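# Ortholog construction, codon-level substitution estimation, synteny and
# gene-remnant filtering. Homology searches themselves are external: this
# module consumes tabular hits (standard 12-column tabular dialect plus
# qlen/slen) and applies the published screening thresholds.

.HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore",
               "qlen", "slen")

#' Read a tabular homology hit file
#'
#' Strict reader for the standard 12-column tabular format extended with
#' qlen and slen (14 columns total); rows with missing fields are rejected.
#'
#' @param path path to a headerless tab-separated hit table.
#' @return data.frame with the 14 standard columns.
#' @export
read_hit_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != length(.HIT_COLS))
    stop(sprintf("expected %d columns (std 12 + qlen,slen), got %d",
                 length(.HIT_COLS), ncol(df)))
  names(df) <- .HIT_COLS
  if (anyNA(df)) stop("hit table contains missing fields")
  df
}

#' Filter homology hits to ortholog candidates and reduce to reciprocal best hits
#'
#' Applies the ortholog screen — identity >= \code{min_identity}, length
#' difference (relative to the longer sequence) <= \code{max_len_diff},
#' E-value <= \code{max_evalue} — then, when a gene-to-genome map is given,
#' reduces each genome pair to reciprocal best hits. Best = lowest E-value,
#' ties broken by higher identity, then higher bit score, then lexicographic
#' subject id.
#'
#' @param hits hit data.frame (see \code{\link{read_hit_table}}).
#' @param gene_genome optional named character vector mapping gene id to
#'   genome id; required for the RBH reduction.
#' @param min_identity,max_len_diff,max_evalue thresholds
#'   (defaults 60, 0.20, 1e-20).
#' @return filtered hit data.frame; with \code{gene_genome}, only RBH pairs
#'   (one row per ordered pair).
#' @export
filter_ortholog_hits <- function(hits, gene_genome = NULL,
                                 min_identity = 60, max_len_diff = 0.20,
                                 max_evalue = 1e-20) {
  if (!all(c("qlen", "slen") %in% names(hits)))
    stop("hits must carry qlen and slen columns")
  len_diff <- abs(hits$qlen - hits$slen) / pmax(hits$qlen, hits$slen)
  keep <- hits$pident >= min_identity & len_diff <= max_len_diff &
    hits$evalue <= max_evalue & hits$qseqid != hits$sseqid
  f <- hits[keep, , drop = FALSE]
  if (is.null(gene_genome) || nrow(f) == 0L) return(f)
  qg <- gene_genome[f$qseqid]; sg <- gene_genome[f$sseqid]
  if (anyNA(qg) || anyNA(sg)) stop("gene_genome map misses some gene ids")
  f <- f[qg != sg, , drop = FALSE]
  qg <- gene_genome[f$qseqid]; sg <- gene_genome[f$sseqid]
  # best hit per (query, target genome)
  ord <- order(f$qseqid, sg, f$evalue, -f$pident, -f$bitscore, f$sseqid)
  fo <- f[ord, , drop = FALSE]
  best <- fo[!duplicated(paste(fo$qseqid, sg[ord])), , drop = FALSE]
  key <- paste(best$qseqid, best$sseqid)
  rev_key <- paste(best$sseqid, best$qseqid)
  best[key %in% rev_key, , drop = FALSE]
}

#' Build the core ortholog set across genomes
#'
#' Ortholog groups are full reciprocal-best-hit cliques: a candidate group
#' (one gene per genome, seeded from each gene of the first genome and its
#' RBH partners) is accepted as core only if every pair of members is an
#' RBH pair. Clique construction avoids chaining paralogs through
#' transitive closure; a single-linkage alternative is available.
#'
#' @param rbh RBH hit data.frame from \code{\link{filter_ortholog_hits}}.
#' @param gene_genome named character vector: gene id -> genome id.
#' @param genomes character vector of all genome ids in the panel.
#' @param linkage \code{"clique"} (default) or \code{"single"}
#'   (connected components with one gene per genome).
#' @return data.frame of core groups: \code{group_id}, one column per
#'   genome holding the member gene id, and \code{complete} (all TRUE).
#' @export
build_core_set <- function(rbh, gene_genome, genomes,
                           linkage = c("clique", "single")) {
  linkage <- match.arg(linkage)
  edges <- unique(data.frame(a = pmin(rbh$qseqid, rbh$sseqid),
                             b = pmax(rbh$qseqid, rbh$sseqid),
                             stringsAsFactors = FALSE))
  ekey <- paste(edges$a, edges$b)
  has_edge <- function(x, y) paste(pmin(x, y), pmax(x, y)) %in% ekey
  # partner of gene g in genome t (unique under RBH), NA if none
  partners <- function(g) {
    hit <- c(edges$b[edges$a == g], edges$a[edges$b == g])
    stats::setNames(hit, gene_genome[hit])
  }
  g1 <- genomes[1L]
  seeds <- unique(c(edges$a, edges$b))
  seeds <- seeds[gene_genome[seeds] == g1]
  groups <- list()
  for (s in sort(seeds)) {
    if (linkage == "clique") {
      p <- partners(s)
      members <- stats::setNames(c(s, unname(p)), c(g1, names(p)))
      if (anyDuplicated(names(members))) next  # paralog conflict: exclude
      if (!all(genomes %in% names(members))) next
      members <- members[genomes]
      pairs <- utils::combn(members, 2L)
      if (!all(has_edge(pairs[1L, ], pairs[2L, ]))) next
    } else {
      # single linkage: the RBH connected component containing the seed
      comp <- s
      frontier <- s
      while (length(frontier)) {
        nxt <- setdiff(unique(unlist(lapply(frontier, partners))), comp)
        comp <- c(comp, nxt)
        frontier <- nxt
      }
      members <- stats::setNames(comp, gene_genome[comp])
      if (anyDuplicated(names(members))) next  # chained paralogs: exclude
      if (!all(genomes %in% names(members))) next
      members <- members[genomes]
    }
    groups[[length(groups) + 1L]] <- members
  }
  if (length(groups) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(character()), length(genomes) + 2L),
      c("group_id", genomes, "complete")))
    return(out)
  }
  out <- as.data.frame(do.call(rbind, groups), stringsAsFactors = FALSE)
  names(out) <- genomes
  out <- out[order(out[[1L]]), , drop = FALSE]
  out <- cbind(group_id = sprintf("OG%04d", seq_len(nrow(out))), out,
               complete = TRUE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Codon-aware pairwise alignment of two coding sequences
#'
#' Globally aligns the two translations (Needleman-Wunsch, BLOSUM62, affine
#' gaps) and back-translates the alignment onto codons. Codon columns
#' containing a gap or an ambiguity character are dropped, yielding an
#' ungapped codon alignment ready for substitution counting.
#'
#' @param cds_a,cds_b in-frame stop-free coding sequences.
#' @param gap_opening,gap_extension affine gap penalties (defaults 10, 0.5).
#' @return list with codon vectors \code{a} and \code{b} (equal length) and
#'   \code{dropped}, the number of excluded columns.
#' @export
codon_align_pair <- function(cds_a, cds_b, gap_opening = 10,
                             gap_extension = 0.5) {
  pa <- translate_cds(cds_a)
  pb <- translate_cds(cds_b)
  if (grepl("\\*", pa) || grepl("\\*", pb))
    stop("internal stop codon: sequences must be in frame and stop-free")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = "BLOSUM62", gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  codons_a <- substring(cds_a, seq(1L, nchar(cds_a) - 2L, 3L),
                        seq(3L, nchar(cds_a), 3L))
  codons_b <- substring(cds_b, seq(1L, nchar(cds_b) - 2L, 3L),
                        seq(3L, nchar(cds_b), 3L))
  ia <- 0L; ib <- 0L
  keep_a <- integer(); keep_b <- integer()
  for (k in seq_along(sa)) {
    ga <- sa[k] == "-"; gb <- sb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) { keep_a <- c(keep_a, ia); keep_b <- c(keep_b, ib) }
  }
  a <- codons_a[keep_a]; b <- codons_b[keep_b]
  clean <- !grepl("[^ACGT]", a) & !grepl("[^ACGT]", b)
  dropped <- length(sa) - sum(clean)
  a <- a[clean]; b <- b[clean]
  if (length(a) == 0L) stop("no aligned codon columns remain")
  list(a = a, b = b, dropped = dropped)
}

.is_transition <- function(x, y) {
  (x %in% c("A", "G") & y %in% c("A", "G")) |
    (x %in% c("C", "T") & y %in% c("C", "T"))
}

# expected synonymous sites of one codon under transition/transversion
# ratio R: per position the transition route has probability R/(R+1) and
# each transversion 1/(2(R+1)); changes producing stops count nonsynonymous.
.syn_sites_codon <- function(codon, R) {
  aa <- .GENETIC_CODE[[codon]]
  bases <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (nb in setdiff(.BASES, bases[pos])) {
      mut <- bases
      mut[pos] <- nb
      mcod <- paste(mut, collapse = "")
      w <- if (.is_transition(bases[pos], nb)) R / (R + 1) else 1 / (2 * (R + 1))
      if (.GENETIC_CODE[[mcod]] == aa) s <- s + w
    }
  }
  s
}

# enumerate substitution pathways between two codons; returns average
# synonymous and nonsynonymous step counts over pathways that avoid stop
# codons (falling back to all pathways when every route crosses a stop).
.pathway_counts <- function(ca, cb) {
  ba <- strsplit(ca, "")[[1]]
  bb <- strsplit(cb, "")[[1]]
  diffpos <- which(ba != bb)
  k <- length(diffpos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(diffpos) else {
    idx <- .permutations(k)
    lapply(seq_len(nrow(idx)), function(i) diffpos[idx[i, ]])
  }
  walk <- function(order) {
    cur <- ba
    sd <- 0; nd <- 0
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- bb[pos]
      aa1 <- .GENETIC_CODE[[paste(cur, collapse = "")]]
      aa2 <- .GENETIC_CODE[[paste(nxt, collapse = "")]]
      if (aa2 == "*" || aa1 == "*") return(NULL)
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- lapply(perms, walk)
  ok <- res[!vapply(res, is.null, TRUE)]
  if (length(ok) == 0L) {
    # all pathways cross a stop codon: average over them anyway, counting
    # stop-crossing steps as nonsynonymous
    walk_all <- function(order) {
      cur <- ba; sd <- 0; nd <- 0
      for (pos in order) {
        nxt <- cur; nxt[pos] <- bb[pos]
        aa1 <- .GENETIC_CODE[[paste(cur, collapse = "")]]
        aa2 <- .GENETIC_CODE[[paste(nxt, collapse = "")]]
        if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    }
    ok <- lapply(perms, walk_all)
  }
  colMeans(do.call(rbind, ok))
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  prev <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[prev], nrow(prev)))
  }))
}

#' Modified Nei-Gojobori dN/dS with Jukes-Cantor correction
#'
#' Site-counting estimator of synonymous (dS) and nonsynonymous (dN)
#' substitution rates. Expected synonymous site counts per codon are
#' weighted by the transition/transversion ratio R (transition route
#' probability R/(R+1), each transversion 1/(2(R+1)); R = 0.5 recovers the
#' unweighted 1/3-per-route counting of the original method). Site counts
#' are averaged over the two sequences; observed differences at codons
#' differing in 2-3 positions are averaged with equal weight over
#' substitution pathways that avoid stop codons. The Jukes-Cantor
#' correction d = -(3/4) ln(1 - 4p/3) is applied to both proportions;
#' p >= 3/4 leaves the corresponding rate undefined (NA, flagged).
#'
#' @param alignment ungapped codon alignment from
#'   \code{\link{codon_align_pair}} (list with codon vectors \code{a},
#'   \code{b}).
#' @param R transition/transversion ratio; \code{NULL} (default) estimates
#'   it from fourfold-degenerate sites of the alignment via
#'   \code{\link{estimate_tstv}}.
#' @return object of class \code{substitution_estimate}: list with
#'   \code{dN, dS, omega, S, N, Sd, Nd, R, flag} where \code{flag} is
#'   \code{"ok"}, \code{"saturated"} (p >= 3/4) or \code{"no_sites"}.
#' @export
dnds_modified_ng <- function(alignment, R = NULL) {
  a <- alignment$a; b <- alignment$b
  if (length(a) != length(b) || length(a) == 0L)
    stop("alignment must contain equal-length nonempty codon vectors")
  if (is.null(R)) R <- estimate_tstv(alignment)
  if (R <= 0) stop("R must be positive")
  syn_cache <- new.env(parent = emptyenv())
  ssites <- function(cod) {
    if (is.null(syn_cache[[cod]])) syn_cache[[cod]] <- .syn_sites_codon(cod, R)
    syn_cache[[cod]]
  }
  Sa <- sum(vapply(a, ssites, 0))
  Sb <- sum(vapply(b, ssites, 0))
  S <- (Sa + Sb) / 2
  N <- 3 * length(a) - S
  counts <- vapply(seq_along(a), function(i) .pathway_counts(a[i], b[i]), c(sd = 0, nd = 0))
  Sd <- sum(counts["sd", ])
  Nd <- sum(counts["nd", ])
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  flag <- "ok"
  if (S == 0 || N == 0) flag <- "no_sites"
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  dS <- if (is.na(ps)) NA_real_ else jc(ps)
  dN <- if (is.na(pn)) NA_real_ else jc(pn)
  if ((!is.na(ps) && ps >= 0.75) || (!is.na(pn) && pn >= 0.75))
    flag <- "saturated"
  omega <- if (!is.na(dN) && !is.na(dS) && dS > 0) dN / dS else NA_real_
  structure(list(dN = dN, dS = dS, omega = omega, S = S, N = N,
                 Sd = Sd, Nd = Nd, R = R, flag = flag),
            class = "substitution_estimate")
}

#' @export
print.substitution_estimate <- function(x, ...) {
  cat(sprintf("<substitution_estimate> dN=%.4f dS=%.4f (S=%.1f N=%.1f R=%.2f, %s)\n",
              x$dN, x$dS, x$S, x$N, x$R, x$flag))
  invisible(x)
}

#' Estimate the transition/transversion ratio from fourfold sites
#'
#' Counts transition and transversion differences at third positions of
#' codons whose first two positions match and whose family is fourfold
#' degenerate, and returns their ratio (per-route: transitions / total
#' transversions). Falls back to \code{fallback} when no informative
#' difference exists.
#'
#' @param alignment codon alignment (list with \code{a}, \code{b}).
#' @param fallback value returned when the ratio is inestimable (default
#'   0.5, i.e. no bias).
#' @return positive numeric R.
#' @export
estimate_tstv <- function(alignment, fallback = 0.5) {
  a <- alignment$a; b <- alignment$b
  fourfold <- vapply(a, function(cod) {
    stem <- substr(cod, 1L, 2L)
    length(unique(.GENETIC_CODE[paste0(stem, .BASES)])) == 1L
  }, TRUE)
  same_stem <- substr(a, 1L, 2L) == substr(b, 1L, 2L)
  idx <- which(fourfold & same_stem & substr(a, 3L, 3L) != substr(b, 3L, 3L))
  if (length(idx) == 0L) return(fallback)
  ts <- sum(.is_transition(substr(a[idx], 3L, 3L), substr(b[idx], 3L, 3L)))
  tv <- length(idx) - ts
  if (tv == 0L || ts == 0L) return(fallback)
  ts / tv
}

#' Partition positively selected ortholog groups across three strain pairs
#'
#' For each strain pair, counts core groups with dN > dS (both defined),
#' and partitions the three sets of positively selected group ids into the
#' seven exclusive Venn regions.
#'
#' @param estimates named list of three data.frames (one per pair), each
#'   with columns \code{group_id, dN, dS} (NA = undefined, excluded).
#' @return list with \code{per_pair} counts, \code{venn} (exclusive region
#'   counts), \code{computable} (groups with defined estimates per pair)
#'   and \code{sets} (the group-id sets).
#' @export
positive_selection_partition <- function(estimates) {
  if (length(estimates) != 3L || is.null(names(estimates)))
    stop("estimates must be a named list of three pair tables")
  sets <- lapply(estimates, function(df) {
    ok <- !is.na(df$dN) & !is.na(df$dS)
    df$group_id[ok & df$dN > df$dS]
  })
  computable <- vapply(estimates, function(df)
    sum(!is.na(df$dN) & !is.na(df$dS)), 0L)
  nm <- names(estimates)
  A <- sets[[1L]]; B <- sets[[2L]]; C <- sets[[3L]]
  venn <- c(
    stats::setNames(length(setdiff(setdiff(A, B), C)), paste0(nm[1L], "_only")),
    stats::setNames(length(setdiff(setdiff(B, A), C)), paste0(nm[2L], "_only")),
    stats::setNames(length(setdiff(setdiff(C, A), B)), paste0(nm[3L], "_only")),
    stats::setNames(length(setdiff(intersect(A, B), C)), paste(nm[1L], nm[2L], sep = "&")),
    stats::setNames(length(setdiff(intersect(A, C), B)), paste(nm[1L], nm[3L], sep = "&")),
    stats::setNames(length(setdiff(intersect(B, C), A)), paste(nm[2L], nm[3L], sep = "&")),
    stats::setNames(length(intersect(intersect(A, B), C)), paste(nm, collapse = "&")))
  list(per_pair = vapply(sets, length, 0L), venn = venn,
       computable = computable, sets = sets)
}

#' Compare ortholog order and orientation between two genomes
#'
#' Linearizes both chromosomes at their replication origins, emits one line
#' per ortholog pair (origin-relative positions and a same-strand flag) and
#' counts breakpoints: consecutive orthologs along genome A whose
#' counterparts in B are not adjacent with preserved relative orientation
#' (signed adjacency).
#'
#' @param orthologs data.frame with columns \code{gene_a, gene_b}.
#' @param coords_a,coords_b data.frames with \code{gene_id, start, end,
#'   strand} for each genome.
#' @param map_a,map_b \code{replichore_map}s (their oriC re-zeroes the
#'   coordinates); pass \code{oriC = 0} maps to skip re-zeroing.
#' @return object of class \code{synteny_comparison}: list with
#'   \code{pairs} (data.frame \code{gene_a, gene_b, pos_a, pos_b,
#'   same_strand}) and \code{breakpoints}.
#' @export
synteny_compare <- function(orthologs, coords_a, coords_b, map_a, map_b) {
  pick <- function(coords, ids) {
    i <- match(ids, coords$gene_id)
    coords[i, , drop = FALSE]
  }
  ca <- pick(coords_a, orthologs$gene_a)
  cb <- pick(coords_b, orthologs$gene_b)
  ok <- !is.na(ca$start) & !is.na(cb$start)
  if (!all(ok)) {
    warning(sprintf("%d ortholog pairs lack coordinates; skipped", sum(!ok)))
    ca <- ca[ok, , drop = FALSE]; cb <- cb[ok, , drop = FALSE]
  }
  La <- map_a$genome_length; Lb <- map_b$genome_length
  pos_a <- (((ca$start + ca$end) / 2) - map_a$oriC) %% La
  pos_b <- (((cb$start + cb$end) / 2) - map_b$oriC) %% Lb
  same <- ca$strand == cb$strand
  ordA <- order(pos_a)
  pairs <- data.frame(gene_a = ca$gene_id[ordA], gene_b = cb$gene_id[ordA],
                      pos_a = pos_a[ordA], pos_b = pos_b[ordA],
                      same_strand = same[ordA], stringsAsFactors = FALSE)
  # signed rank of each counterpart along B
  rankB <- rank(pairs$pos_b, ties.method = "first")
  signed <- ifelse(pairs$same_strand, rankB, -rankB)
  bp <- 0L
  n <- nrow(pairs)
  if (n >= 2L)
    bp <- sum(signed[-1L] != signed[-n] + 1L)
  structure(list(pairs = pairs, breakpoints = as.integer(bp)),
            class = "synteny_comparison")
}

#' Filter translated-search hits of intergenic segments to gene remnants
#'
#' Applies the remnant screen (identity >= \code{min_identity}, aligned
#' length >= \code{min_aa} amino acids, E-value < \code{max_evalue}),
#' merges overlapping passing hits on the same intergenic segment, computes
#' per-region G+C from the genome, and summarizes (hit count, mean and SD
#' of region G+C%).
#'
#' @param hits data.frame of translated-search hits: columns \code{qseqid}
#'   (intergenic segment id), \code{sseqid} (gene), \code{pident},
#'   \code{length} (aligned amino acids), \code{evalue}, \code{qstart},
#'   \code{qend} (nt within the segment, 1-based inclusive).
#' @param segments intergenic segment table from
#'   \code{\link{extract_intergenic}}.
#' @param genome the \code{genome_record} the segments came from.
#' @param min_identity,min_aa,max_evalue thresholds (defaults 30, 15, 1e-3).
#' @return list with \code{remnants} (data.frame: segment id, genomic
#'   coords, best-hit gene, identity, aligned aa, E-value, region G+C) and
#'   \code{summary} (n_hits, mean_gc_pct, sd_gc_pct).
#' @export
filter_remnant_hits <- function(hits, segments, genome,
                                min_identity = 30, min_aa = 15,
                                max_evalue = 1e-3) {
  keep <- hits$pident >= min_identity & hits$length >= min_aa &
    hits$evalue < max_evalue
  f <- hits[keep, , drop = FALSE]
  if (nrow(f) == 0L)
    return(list(remnants = data.frame(), summary = data.frame(
      n_hits = 0L, mean_gc_pct = NA_real_, sd_gc_pct = NA_real_)))
  out <- list()
  for (seg_id in unique(f$qseqid)) {
    sh <- f[f$qseqid == seg_id, , drop = FALSE]
    seg <- segments[segments$segment_id == seg_id, , drop = FALSE]
    if (nrow(seg) == 0L) stop("hit references unknown segment: ", seg_id)
    ir <- IRanges::reduce(IRanges::IRanges(start = pmin(sh$qstart, sh$qend),
                                           end = pmax(sh$qstart, sh$qend)))
    for (j in seq_along(ir)) {
      r_start <- seg$start + IRanges::start(ir)[j] - 1L  # genomic, 0-based
      r_end <- seg$start + IRanges::end(ir)[j]
      inside <- sh[pmin(sh$qstart, sh$qend) <= IRanges::end(ir)[j] &
                     pmax(sh$qstart, sh$qend) >= IRanges::start(ir)[j], ,
                   drop = FALSE]
      best <- inside[order(inside$evalue, -inside$pident), , drop = FALSE][1L, ]
      region_seq <- slice_genome(genome, r_start, r_end)
      out[[length(out) + 1L]] <- data.frame(
        segment_id = seg_id, start = r_start, end = r_end,
        best_hit_gene = best$sseqid, pident = best$pident,
        aligned_aa = best$length, evalue = best$evalue,
        gc_pct = 100 * gc_content(region_seq), stringsAsFactors = FALSE)
    }
  }
  remnants <- do.call(rbind, out)
  list(remnants = remnants,
       summary = data.frame(n_hits = nrow(remnants),
                            mean_gc_pct = mean(remnants$gc_pct),
                            sd_gc_pct = stats::sd(remnants$gc_pct)))
}
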