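#' GC-skew profile of a genome
#'
#' Computes (G - C) / (G + C) in consecutive windows along the genome
#' (default 10 kb, non-overlapping). On a circular genome the final window
#' wraps across the junction. Windows with no G or C yield skew 0 by
#' convention. The cumulative series is the running sum of per-window skews
#' and is the substrate for origin/terminus prediction.
#'
#' @param genome a \code{genome_record}.
#' @param window window size in nt (default 10000).
#' @param step step between window starts; defaults to \code{window}
#'   (non-overlapping). Smaller steps give overlapping windows.
#' @return object of class \code{skew_profile}: data.frame with columns
#'   \code{start, end, skew, cumulative}, plus attributes \code{window},
#'   \code{step} and \code{genome_length}.
#' @export
gc_skew_profile <- function(genome, window = 10000L, step = window) {
  L <- genome$length
  if (window > L) stop("window exceeds genome length")
  r <- charToRaw(genome$sequence)
  isG <- as.integer(r == as.raw(71L))
  isC <- as.integer(r == as.raw(67L))
  if (genome$topology == "circular") {
    isG <- c(isG, isG[seq_len(min(window, L))])
    isC <- c(isC, isC[seq_len(min(window, L))])
  }
  cumG <- c(0, cumsum(isG))
  cumC <- c(0, cumsum(isC))
  starts <- seq(0L, L - 1L, by = step)
  ends <- starts + window
  if (genome$topology != "circular") {
    keep <- ends <= L
    starts <- starts[keep]; ends <- ends[keep]
  }
  g <- cumG[ends + 1L] - cumG[starts + 1L]
  cc <- cumC[ends + 1L] - cumC[starts + 1L]
  skew <- ifelse(g + cc == 0, 0, (g - cc) / (g + cc))
  df <- data.frame(start = starts, end = ends, skew = skew,
                   cumulative = cumsum(skew))
  attr(df, "window") <- window
  attr(df, "step") <- step
  attr(df, "genome_length") <- L
  class(df) <- c("skew_profile", "data.frame")
  df
}

#' Predict the origin and terminus of replication from cumulative GC skew
#'
#' The leading strand is G(+T) rich, so the cumulative (G - C) skew rises
#' from oriC to ter along increasing coordinates: oriC is placed at the
#' global minimum of the cumulative curve and ter at the global maximum
#' (positions are window boundaries, modulo genome length). A flat
#' cumulative curve means there is no replichore structure to detect.
#'
#' @param profile a \code{skew_profile}.
#' @return list with \code{oriC}, \code{ter} (nt positions) and the
#'   cumulative-curve amplitude \code{amplitude}.
#' @export
predict_ori_ter <- function(profile) {
  cum <- profile$cumulative
  L <- attr(profile, "genome_length")
  if (max(cum) - min(cum) == 0)
    stop("no replichore structure: cumulative GC skew is flat")
  # boundary after window i is end[i]; the curve starts at 0 before window 1
  curve <- c(0, cum)
  bounds <- c(profile$start[1L], profile$end) %% L
  oriC <- bounds[which.min(curve)]
  ter <- bounds[which.max(curve)]
  list(oriC = as.integer(oriC), ter = as.integer(ter),
       amplitude = max(cum) - min(cum))
}

#' Scan for DnaA boxes near a putative origin
#'
#' Finds occurrences of the 9-mer DnaA-box consensus \code{TTATCCACA} with
#' at most \code{max_mismatch} mismatches, on both strands, within
#' \code{radius} nt of the given position (wrapping on circular genomes).
#'
#' @param genome a \code{genome_record}.
#' @param oriC center of the scan window (nt).
#' @param radius scan radius in nt (default 5000).
#' @param max_mismatch allowed mismatches (default 1).
#' @return data.frame with columns \code{position} (0-based genomic start of
#'   the 9-mer), \code{strand} and \code{mismatches}.
#' @export
find_dnaa_boxes <- function(genome, oriC, radius = 5000L, max_mismatch = 1L) {
  L <- genome$length
  lo <- oriC - radius
  hi <- oriC + radius
  if (genome$topology == "circular") {
    start <- ((lo %% L) + L) %% L
    len <- min(hi - lo, L)
    region <- slice_genome(genome, start, start + len)
    offset <- start
  } else {
    start <- max(0L, lo); end <- min(L, hi)
    region <- slice_genome(genome, start, end)
    offset <- start
  }
  k <- nchar(.DNAA_BOX)
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") region else revcomp(region)
    n <- nchar(s)
    if (n < k) next
    m <- matrix(utf8ToInt(s)[outer(seq_len(n - k + 1L) - 1L, seq_len(k), `+`)],
                ncol = k)
    mm <- rowSums(m != matrix(utf8ToInt(.DNAA_BOX), nrow(m), k, byrow = TRUE))
    pos0 <- which(mm <= max_mismatch)
    if (length(pos0)) {
      # map back to genomic coordinates of the motif start on the + strand
      p <- if (strand == "+") pos0 - 1L else n - (pos0 - 1L) - k
      hits[[strand]] <- data.frame(position = (offset + p) %% L,
                                   strand = strand,
                                   mismatches = mm[pos0],
                                   stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(position = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out[order(out$position), , drop = FALSE]
}

#' Build a replichore map and classify genes as leading or lagging
#'
#' Replichore 1 is the arc from oriC to ter in the direction of increasing
#' coordinates; on that arc the plus strand is replicated continuously, so a
#' plus-strand gene there is leading-strand encoded (and a minus-strand gene
#' lagging); the rule reverses on replichore 2. Genes straddling a boundary
#' are classified by their midpoint; a midpoint falling exactly on ter
#' counts as replichore 1.
#'
#' @param genome a \code{genome_record}.
#' @param annotations a \code{gene_annotation} data.frame.
#' @param oriC,ter replication origin and terminus positions (nt); usually
#'   from \code{\link{predict_ori_ter}}, overridable by the user.
#' @return object of class \code{replichore_map}: list with \code{oriC},
#'   \code{ter} and \code{classes}, a data.frame (\code{gene_id, strand,
#'   replichore, strand_class}).
#' @export
replichore_map <- function(genome, annotations, oriC, ter) {
  if (oriC == ter) stop("oriC and ter must differ")
  L <- genome$length
  mid <- ((annotations$start + annotations$end) / 2) %% L
  arc <- function(pos) {
    # position of pos on the circle relative to oriC, in [0, L)
    d_ori <- (pos - oriC) %% L
    d_ter <- (ter - oriC) %% L
    ifelse(d_ori > 0 & d_ori <= d_ter, 1L, 2L)
  }
  rep_arc <- arc(mid)
  leading <- (annotations$strand == "+" & rep_arc == 1L) |
    (annotations$strand == "-" & rep_arc == 2L)
  classes <- data.frame(gene_id = annotations$gene_id,
                        strand = annotations$strand,
                        replichore = rep_arc,
                        strand_class = ifelse(leading, "leading", "lagging"),
                        stringsAsFactors = FALSE)
  structure(list(oriC = as.integer(oriC), ter = as.integer(ter),
                 genome_length = L, classes = classes),
            class = "replichore_map")
}

#' @rdname replichore_map
#' @param gene a single-row \code{gene_annotation} (or any list with
#'   \code{start}, \code{end}, \code{strand}).
#' @param map a \code{replichore_map}.
#' @export
assign_strand_class <- function(gene, map) {
  L <- map$genome_length
  mid <- ((gene$start + gene$end) / 2) %% L
  d_ori <- (mid - map$oriC) %% L
  d_ter <- (map$ter - map$oriC) %% L
  rep_arc <- if (d_ori > 0 && d_ori <= d_ter) 1L else 2L
  if ((gene$strand == "+") == (rep_arc == 1L)) "leading" else "lagging"
}

#' @export
print.replichore_map <- function(x, ...) {
  cat(sprintf("<replichore_map> oriC=%d ter=%d; %d genes (%d leading / %d lagging)\n",
              x$oriC, x$ter, nrow(x$classes),
              sum(x$classes$strand_class == "leading"),
              sum(x$classes$strand_class == "lagging")))
  invisible(x)
}
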