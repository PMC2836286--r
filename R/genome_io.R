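#' Construct a genome record
#'
#' A genome record holds a single replicon: an accession-style identifier,
#' the nucleotide sequence (uppercase \code{A/C/G/T/N}) and an explicit
#' topology. Circular topology matters downstream: sliding windows wrap,
#' genes may span the junction, and the wrap dinucleotide is counted.
#'
#' @param id accession or strain identifier.
#' @param sequence nucleotide string; lowercase input is uppercased.
#' @param topology \code{"circular"} or \code{"linear"}.
#' @return An object of class \code{genome_record} with fields \code{id},
#'   \code{sequence}, \code{topology} and \code{length}.
#' @export
genome_record <- function(id, sequence, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("genome sequence is empty")
  if (grepl("[^ACGTN]", sequence))
    stop("genome sequence contains characters outside {A,C,G,T,N}")
  structure(list(id = id, sequence = sequence, topology = topology,
                 length = nchar(sequence)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d nt, %s, G+C %.1f%%\n",
              x$id, x$length, x$topology, 100 * gc_content(x$sequence)))
  invisible(x)
}

#' Build a gene annotation table
#'
#' Coordinates are 0-based half-open throughout the package; GenBank's
#' 1-based inclusive coordinates are converted at the parsing boundary.
#' A gene spanning the circular junction is stored unwrapped with
#' \code{end > genome length} and interpreted modulo the length when sliced.
#'
#' @param gene_id character vector of identifiers.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand \code{"+"} or \code{"-"}.
#' @param kind one of \code{"CDS"}, \code{"rRNA"}, \code{"tRNA"},
#'   \code{"other_structural_RNA"}.
#' @param translation optional amino-acid strings (NA when absent).
#' @return data.frame of class \code{gene_annotation}.
#' @export
gene_annotation <- function(gene_id, start, end, strand, kind,
                            translation = NA_character_) {
  kinds <- c("CDS", "rRNA", "tRNA", "other_structural_RNA")
  stopifnot(all(strand %in% c("+", "-")), all(kind %in% kinds),
            all(start >= 0), all(end > start))
  df <- data.frame(gene_id = as.character(gene_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), kind = as.character(kind),
                   translation = as.character(translation),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_annotation", class(df))
  df
}

# reverse complement of a plain character string
revcomp <- function(x) {
  vapply(x, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    "", USE.NAMES = FALSE)
}

# Slice [start, end) from a genome, honouring circular wrap (end may exceed L)
# and strand (reverse complement for '-').
slice_genome <- function(genome, start, end, strand = "+") {
  L <- genome$length
  if (end > L) {
    if (genome$topology != "circular")
      stop("interval beyond the end of a linear genome")
    s <- paste0(substr(genome$sequence, start + 1L, L),
                substr(genome$sequence, 1L, end - L))
  } else {
    s <- substr(genome$sequence, start + 1L, end)
  }
  if (strand == "-") s <- revcomp(s) else s
}

#' Translate a coding sequence (bacterial code)
#'
#' Uses the standard amino-acid assignments (identical to translation
#' table 11 for sense codons); the initiator codon is rendered as M when it
#' is one of the bacterial start codons. Codons containing non-ACGT
#' characters translate to X.
#'
#' @param cds in-frame nucleotide string without the stop codon.
#' @return amino-acid string.
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  codons <- substring(cds, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  aa <- unname(.GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  if (length(aa) > 0L && codons[1L] %in% .START_CODONS) aa[1L] <- "M"
  paste(aa, collapse = "")
}

# --- GenBank flatfile parsing ------------------------------------------------

# parse a GenBank location string into (start, end, strand) in 0-based
# half-open convention; join() spans min..max except across the circular
# junction, where the gene is stored unwrapped (end > L).
.parse_location <- function(loc, genome_length = NA_integer_) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  inner <- gsub("complement\\(|join\\(|order\\(|\\)", "", loc)
  inner <- gsub("[<>]", "", inner)
  parts <- strsplit(inner, ",")[[1]]
  rng <- lapply(parts, function(p) {
    nums <- as.numeric(strsplit(p, "\\.\\.")[[1]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    nums
  })
  starts <- vapply(rng, `[`, 0, 1L)
  ends <- vapply(rng, `[`, 0, 2L)
  if (length(parts) > 1L && !is.na(genome_length) &&
      ends[1L] == genome_length && starts[length(starts)] == 1) {
    # spans the circular junction: unwrap
    start <- starts[1L] - 1
    end <- genome_length + ends[length(ends)]
  } else {
    start <- min(starts) - 1
    end <- max(ends)
  }
  list(start = as.integer(start), end = as.integer(end), strand = strand)
}

#' Read a GenBank flatfile
#'
#' Parses a single-replicon GenBank record: the ORIGIN sequence, topology
#' from the LOCUS line, and every CDS / rRNA / tRNA / other structural-RNA
#' feature as a gene annotation. \code{join()} locations are collapsed to
#' their span on the stated strand; features flagged \code{/pseudo} are
#' skipped. CDS features lacking a \code{/translation} are translated
#' in-house with the bacterial code.
#'
#' @param path path to a GenBank flatfile.
#' @return list with elements \code{genome} (a \code{genome_record}) and
#'   \code{annotations} (a \code{gene_annotation} data.frame).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  topology <- if (length(locus) && grepl("circular", locus[1L],
                                         ignore.case = TRUE))
    "circular" else "linear"
  acc_line <- grep("^(VERSION|ACCESSION|LOCUS)", lines, value = TRUE)
  id <- if (length(acc_line)) strsplit(trimws(acc_line[length(acc_line)]),
                                       "\\s+")[[1]][2L] else "unknown"
  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("GenBank record has no ORIGIN sequence")
  end_rec <- grep("^//", lines)
  end_rec <- if (length(end_rec)) end_rec[end_rec > ori[1L]][1L] else
    length(lines) + 1L
  seq_lines <- lines[(ori[1L] + 1L):(end_rec - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("GenBank record has an empty sequence")
  genome <- genome_record(id, sequence, topology)

  feat_start <- grep("^FEATURES", lines)
  ann <- list()
  if (length(feat_start)) {
    flines <- lines[(feat_start[1L] + 1L):(ori[1L] - 1L)]
    # feature keys sit at column 6; qualifiers/continuations at column 22
    is_key <- grepl("^ {5}\\S", flines)
    idx <- which(is_key)
    kinds_map <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
                   ncRNA = "other_structural_RNA",
                   tmRNA = "other_structural_RNA",
                   misc_RNA = "other_structural_RNA")
    n_cds <- 0L
    for (k in seq_along(idx)) {
      first <- flines[idx[k]]
      key <- sub("^ +(\\S+).*$", "\\1", first)
      if (!key %in% names(kinds_map)) next
      to <- if (k < length(idx)) idx[k + 1L] - 1L else length(flines)
      block <- flines[idx[k]:to]
      body <- paste(trimws(c(sub("^ +\\S+ +", "", first), block[-1L])),
                    collapse = "\n")
      if (grepl("(^|\n)/pseudo(\n|$)", body)) next
      # location = leading text up to the first qualifier line
      loc <- strsplit(body, "\n/")[[1]][1L]
      loc <- gsub("\\s", "", loc)
      pos <- .parse_location(loc, genome$length)
      qual <- function(name) {
        m <- regmatches(body, regexpr(sprintf('/%s="[^"]*"', name), body))
        if (length(m)) gsub("\\s", "", sub(sprintf('/%s="', name), "",
                                           sub('"$', "", m))) else NA_character_
      }
      gid <- qual("locus_tag")
      if (is.na(gid)) gid <- qual("gene")
      if (is.na(gid)) {
        n_cds <- n_cds + 1L
        gid <- sprintf("%s_f%03d", id, k)
      }
      tr <- if (key == "CDS") qual("translation") else NA_character_
      if (key == "CDS" && is.na(tr)) {
        cds_seq <- slice_genome(genome, pos$start, pos$end, pos$strand)
        if (nchar(cds_seq) %% 3L == 0L) {
          tr <- translate_cds(substr(cds_seq, 1L, nchar(cds_seq) - 3L))
        }
      }
      ann[[length(ann) + 1L]] <-
        data.frame(gene_id = gid, start = pos$start, end = pos$end,
                   strand = pos$strand, kind = kinds_map[[key]],
                   translation = tr, stringsAsFactors = FALSE)
    }
  }
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(gene_id = character(), start = integer(), end = integer(),
               strand = character(), kind = character(),
               translation = character(), stringsAsFactors = FALSE)
  class(annotations) <- c("gene_annotation", "data.frame")
  list(genome = genome, annotations = annotations)
}

#' Read a genome from FASTA plus an annotation TSV
#'
#' Fallback input route when no GenBank flatfile is available: a single-
#' record FASTA and a tab-separated annotation table with columns
#' \code{gene_id, start, end, strand, kind} (0-based half-open coordinates)
#' and optionally \code{translation}.
#'
#' @param fasta_path single-record FASTA file.
#' @param annotation_path annotation TSV.
#' @param topology genome topology.
#' @return list with \code{genome} and \code{annotations}.
#' @export
read_fasta_genome <- function(fasta_path, annotation_path = NULL,
                              topology = "circular") {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) != 1L) stop("expected a single-replicon FASTA")
  genome <- genome_record(sub("\\s.*$", "", names(ss)[1L]),
                          as.character(ss[[1L]]), topology)
  annotations <- NULL
  if (!is.null(annotation_path)) annotations <- read_annotation_tsv(annotation_path)
  list(genome = genome, annotations = annotations)
}

#' @rdname read_fasta_genome
#' @param path annotation TSV path.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "start", "end", "strand", "kind")
  if (!all(need %in% names(df)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  if (!"translation" %in% names(df)) df$translation <- NA_character_
  gene_annotation(df$gene_id, df$start, df$end, df$strand, df$kind,
                  df$translation)
}

#' @rdname read_fasta_genome
#' @param annotations a \code{gene_annotation} data.frame.
#' @export
write_annotation_tsv <- function(annotations, path) {
  utils::write.table(
    annotations[, c("gene_id", "start", "end", "strand", "kind")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- coding / intergenic extraction -----------------------------------------

#' Extract coding sequences and their proteins
#'
#' Slices every CDS from the genome (reverse-complementing minus-strand
#' genes), strips the stop codon, translates, and keeps only proteins of at
#' least \code{min_aa} residues — short ORFs are excluded from all codon and
#' proteome statistics. CDS with a length not divisible by 3 or with an
#' internal stop are skipped with a warning rather than aborting the run.
#'
#' @param genome a \code{genome_record}.
#' @param annotations a \code{gene_annotation} data.frame.
#' @param min_aa minimum protein length in residues (default 100).
#' @return data.frame with columns \code{gene_id, cds, protein, start, end,
#'   strand}; the \code{cds} column excludes the stop codon.
#' @export
extract_cds <- function(genome, annotations, min_aa = 100L) {
  cds_ann <- annotations[annotations$kind == "CDS", , drop = FALSE]
  out <- vector("list", nrow(cds_ann))
  skipped <- character()
  for (i in seq_len(nrow(cds_ann))) {
    a <- cds_ann[i, ]
    s <- slice_genome(genome, a$start, a$end, a$strand)
    if (nchar(s) %% 3L != 0L) { skipped <- c(skipped, a$gene_id); next }
    last <- substr(s, nchar(s) - 2L, nchar(s))
    if (last %in% .STOP_CODONS) s <- substr(s, 1L, nchar(s) - 3L)
    if (nchar(s) == 0L) { skipped <- c(skipped, a$gene_id); next }
    prot <- translate_cds(s)
    if (grepl("\\*", prot)) { skipped <- c(skipped, a$gene_id); next }
    if (nchar(prot) < min_aa) next
    out[[i]] <- data.frame(gene_id = a$gene_id, cds = s, protein = prot,
                           start = a$start, end = a$end, strand = a$strand,
                           stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning(sprintf("skipped %d CDS with frame/internal-stop pathologies: %s",
                    length(skipped),
                    paste(utils::head(skipped, 5L), collapse = ", ")))
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L)
    return(data.frame(gene_id = character(), cds = character(),
                      protein = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Extract intergenic regions
#'
#' Returns the complement of the union of all annotated gene spans (CDS and
#' structural RNAs alike). Overlapping genes are merged first; on a circular
#' genome the two pieces flanking the junction are fused into a single
#' wrapping segment (stored unwrapped with \code{end > L}).
#'
#' @param genome a \code{genome_record}.
#' @param annotations a \code{gene_annotation} data.frame.
#' @return list with \code{segments} (data.frame \code{segment_id, start,
#'   end, length, gc}) and \code{concatenated} (single string).
#' @export
extract_intergenic <- function(genome, annotations) {
  L <- genome$length
  empty <- data.frame(segment_id = character(), start = integer(),
                      end = integer(), length = integer(), gc = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(annotations) == 0L) {
    seg <- data.frame(segment_id = paste0(genome$id, "_ig1"), start = 0L,
                      end = L, length = L,
                      gc = gc_content(genome$sequence),
                      stringsAsFactors = FALSE)
    return(list(segments = seg, concatenated = genome$sequence))
  }
  st <- annotations$start
  en <- annotations$end
  # normalize genes stored unwrapped across the junction into two pieces
  wrap <- en > L
  if (any(wrap)) {
    st <- c(st[!wrap], st[wrap], rep(0L, sum(wrap)))
    en <- c(en[!wrap], rep(L, sum(wrap)), en[wrap] - L)
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = st + 1L, end = en))
  gaps <- IRanges::gaps(ir, start = 1L, end = L)
  segs <- data.frame(start = IRanges::start(gaps) - 1L,
                     end = IRanges::end(gaps))
  if (nrow(segs) >= 2L && genome$topology == "circular" &&
      segs$start[1L] == 0L && segs$end[nrow(segs)] == L &&
      !(nrow(segs) == 1L)) {
    # fuse the junction-flanking pieces into one wrapping segment
    first <- segs[1L, ]
    segs <- segs[-1L, , drop = FALSE]
    segs$end[nrow(segs)] <- L + first$end
  }
  if (nrow(segs) == 0L) return(list(segments = empty, concatenated = ""))
  seq <- vapply(seq_len(nrow(segs)), function(i)
    slice_genome(genome, segs$start[i], segs$end[i]), "")
  segs$segment_id <- sprintf("%s_ig%d", genome$id, seq_len(nrow(segs)))
  segs$length <- segs$end - segs$start
  segs$gc <- vapply(seq, gc_content, 0)
  list(segments = segs[, c("segment_id", "start", "end", "length", "gc")],
       concatenated = paste(seq, collapse = ""))
}

#' G+C fraction of a sequence
#'
#' N bases are excluded from both numerator and denominator.
#'
#' @param sequence nucleotide string.
#' @return fraction in [0, 1].
#' @export
gc_content <- function(sequence) {
  counts <- base_counts(sequence)
  tot <- sum(counts)
  if (tot == 0L) stop("gc_content undefined: no A/C/G/T bases")
  unname((counts["G"] + counts["C"]) / tot)
}

#' Per-base counts of a sequence
#'
#' @param sequence nucleotide string.
#' @return named integer vector over A, C, G, T.
#' @export
base_counts <- function(sequence) {
  r <- charToRaw(toupper(sequence))
  c(A = sum(r == as.raw(65L)), C = sum(r == as.raw(67L)),
    G = sum(r == as.raw(71L)), T = sum(r == as.raw(84L)))
}

#' Per-genome composition report
#'
#' Summarizes, for each genome, the genomic, coding and intergenic G+C
#' percentages plus the genome length.
#'
#' @param panels list of lists with elements \code{genome} and
#'   \code{annotations} (as returned by \code{\link{read_genbank}} or
#'   \code{\link{simulate_genome}}).
#' @param path optional TSV output path.
#' @return data.frame with one row per genome.
#' @export
composition_report <- function(panels, path = NULL) {
  rows <- lapply(panels, function(p) {
    cds <- extract_cds(p$genome, p$annotations, min_aa = 0L)
    ig <- extract_intergenic(p$genome, p$annotations)
    data.frame(
      genome = p$genome$id, length = p$genome$length,
      genomic_gc_pct = 100 * gc_content(p$genome$sequence),
      coding_gc_pct = if (nrow(cds)) 100 * gc_content(paste(cds$cds, collapse = "")) else NA_real_,
      intergenic_gc_pct = if (nchar(ig$concatenated)) 100 * gc_content(ig$concatenated) else NA_real_,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
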