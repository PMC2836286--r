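#' Count codons per gene
#'
#' Exact triplet counts over the 64 codons for each coding sequence.
#' Codons containing a non-ACGT character are skipped. The input sequences
#' must be in frame with the stop codon already removed (as produced by
#' \code{\link{extract_cds}}); a trailing stop, if present, is counted in
#' the stop columns but never enters RSCU.
#'
#' @param cds character vector of in-frame coding sequences (optionally
#'   named by gene id) or the data.frame from \code{\link{extract_cds}}.
#' @return integer matrix genes x 64 of class \code{codon_counts}.
#' @export
count_codons <- function(cds) {
  if (is.data.frame(cds)) {
    ids <- cds$gene_id
    cds <- cds$cds
    names(cds) <- ids
  }
  if (length(cds) == 0L) stop("no coding sequences supplied")
  if (any(nchar(cds) == 0L)) stop("empty CDS supplied")
  if (any(nchar(cds) %% 3L != 0L)) stop("CDS length not divisible by 3")
  m <- matrix(0L, nrow = length(cds), ncol = 64L,
              dimnames = list(names(cds), .CODONS))
  for (i in seq_along(cds)) {
    n <- nchar(cds[i])
    codons <- substring(cds[i], seq(1L, n - 2L, 3L), seq(3L, n, 3L))
    tab <- table(factor(codons, levels = .CODONS))
    m[i, ] <- as.integer(tab)
  }
  class(m) <- c("codon_counts", class(m))
  m
}

#' Relative synonymous codon usage
#'
#' For each synonymous family of size n, RSCU of a codon is its count times
#' n divided by the family total — 1 for unbiased usage, n for exclusive
#' usage. Met (ATG), Trp (TGG) and stop codons carry no synonymous choice
#' and are excluded, leaving 59 columns. A family absent from a gene gets
#' RSCU 0 for all its codons.
#'
#' @param counts a \code{codon_counts} matrix (or a single named count
#'   vector over the 64 codons).
#' @return numeric matrix genes x 59 of RSCU values.
#' @export
rscu <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, names(counts)))
  out <- matrix(0, nrow = nrow(counts), ncol = length(.SYN_CODONS),
                dimnames = list(rownames(counts), .SYN_CODONS))
  for (fam in .SYN_FAMILIES) {
    sub <- counts[, fam, drop = FALSE]
    tot <- rowSums(sub)
    nz <- tot > 0
    if (any(nz))
      out[nz, fam] <- length(fam) * sub[nz, , drop = FALSE] / tot[nz]
  }
  out
}

#' G+C and G+T content at synonymous third codon positions
#'
#' Fractions of third-position bases that are G/C (GC3s) and G/T (GT3s),
#' computed over the 59 synonymous codons only (Met, Trp and stops excluded
#' so the third position is free to vary synonymously).
#'
#' @param counts a \code{codon_counts} matrix.
#' @return data.frame with columns \code{gene_id, gc3s, gt3s, syn_codons};
#'   genes without synonymous codons get NA and are flagged.
#' @export
gc3s_gt3s <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, names(counts)))
  third <- substr(.SYN_CODONS, 3L, 3L)
  sub <- counts[, .SYN_CODONS, drop = FALSE]
  tot <- rowSums(sub)
  gc3 <- rowSums(sub[, third %in% c("G", "C"), drop = FALSE]) / tot
  gt3 <- rowSums(sub[, third %in% c("G", "T"), drop = FALSE]) / tot
  gc3[tot == 0] <- NA_real_
  gt3[tot == 0] <- NA_real_
  data.frame(gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             gc3s = unname(gc3), gt3s = unname(gt3),
             syn_codons = unname(tot), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correspondence analysis of an RSCU matrix
#'
#' Standard correspondence analysis: the matrix is normalized to a grand
#' total of 1, row and column masses computed, and the standardized
#' residuals decomposed by SVD. Row (gene) and column (codon) principal
#' coordinates are returned together with the principal-inertia fractions
#' (percent of total inertia per axis, summing to 100). Axis signs are
#' arbitrary. Running the analysis on RSCU values rather than raw counts
#' follows the long-standing practice of codon-usage ordination tools.
#'
#' @param m non-negative matrix (genes x codons), typically from
#'   \code{\link{rscu}}.
#' @param k number of axes to return (default 4).
#' @return object of class \code{ca_result}: list with \code{row_coords},
#'   \code{col_coords}, \code{inertia_pct} (all axes) and \code{k}.
#' @export
correspondence_analysis <- function(m, k = 4L) {
  m <- as.matrix(m)
  keep_col <- colSums(m) > 0
  keep_row <- rowSums(m) > 0
  if (sum(keep_row) < 2L || sum(keep_col) < 2L)
    stop("correspondence analysis needs >= 2 nonzero rows and columns")
  mm <- m[keep_row, keep_col, drop = FALSE]
  P <- mm / sum(mm)
  r <- rowSums(P)
  cmass <- colSums(P)
  S <- (P - outer(r, cmass)) / sqrt(outer(r, cmass))
  sv <- svd(S)
  d <- sv$d
  # drop numerically null dimensions
  tol <- max(dim(S)) * max(d) * .Machine$double.eps
  pos <- d > tol
  if (!any(pos)) {
    # all rows identical: zero inertia, all coordinates zero
    nr <- nrow(m)
    rc <- matrix(0, nr, k, dimnames = list(rownames(m), paste0("Axis", 1:k)))
    cc <- matrix(0, ncol(m), k, dimnames = list(colnames(m), paste0("Axis", 1:k)))
    return(structure(list(row_coords = rc, col_coords = cc,
                          inertia_pct = numeric(0), k = k),
                     class = "ca_result"))
  }
  d <- d[pos]
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  inertia <- d^2
  inertia_pct <- 100 * inertia / sum(inertia)
  kk <- min(k, length(d))
  rowc <- sweep(U[, seq_len(kk), drop = FALSE], 1L, sqrt(r), `/`)
  rowc <- sweep(rowc, 2L, d[seq_len(kk)], `*`)
  colc <- sweep(V[, seq_len(kk), drop = FALSE], 1L, sqrt(cmass), `/`)
  colc <- sweep(colc, 2L, d[seq_len(kk)], `*`)
  # re-embed dropped all-zero rows as NA
  rc <- matrix(NA_real_, nrow(m), kk,
               dimnames = list(rownames(m), paste0("Axis", seq_len(kk))))
  rc[keep_row, ] <- rowc
  cc <- matrix(NA_real_, ncol(m), kk,
               dimnames = list(colnames(m), paste0("Axis", seq_len(kk))))
  cc[keep_col, ] <- colc
  structure(list(row_coords = rc, col_coords = cc,
                 inertia_pct = inertia_pct, k = kk),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat(sprintf("<ca_result> %d genes, %d axes; inertia%%: %s ...\n",
              nrow(x$row_coords), x$k,
              paste(sprintf("%.2f", utils::head(x$inertia_pct, 4L)),
                    collapse = " ")))
  invisible(x)
}

#' Correlate ordination axes with a gene-level trait
#'
#' Pearson correlation of each returned axis with a trait vector aligned to
#' the gene order of the RSCU matrix (e.g. GC3s or GT3s). Axis signs being
#' arbitrary, comparisons across runs should use \code{abs(r)}.
#'
#' @param ca a \code{ca_result}.
#' @param trait numeric vector, one value per gene (NA rows dropped).
#' @return named numeric vector of signed correlations, one per axis.
#' @export
axis_trait_correlation <- function(ca, trait) {
  rc <- ca$row_coords
  if (length(trait) != nrow(rc))
    stop("trait vector length must match the number of genes")
  ok <- stats::complete.cases(rc) & !is.na(trait)
  if (stats::sd(trait[ok]) == 0) stop("trait has zero variance")
  vapply(seq_len(ncol(rc)),
         function(j) stats::cor(rc[ok, j], trait[ok]),
         0)
}

#' Per-codon chi-square tests of leading/lagging strand asymmetry
#'
#' For every codon, a 2x2 contingency test of its count against the count
#' of its synonymous alternatives, on the leading versus lagging gene sets.
#' Testing within the synonymous family keeps strand differences in
#' amino-acid composition from confounding the synonymous-codon signal.
#' No continuity correction is applied; when any expected count falls below
#' 5 the p-value comes from Fisher's exact test instead. P-values are
#' reported raw (no multiplicity correction) to match the conventional
#' p < 0.001 screen; a Bonferroni option is provided.
#'
#' @param leading_counts,lagging_counts \code{codon_counts} matrices (or
#'   aggregate count vectors) for leading- and lagging-strand gene sets.
#' @param alpha significance threshold on p (default 0.001).
#' @param bonferroni apply Bonferroni correction across tested codons.
#' @return data.frame with one row per tested codon: counts, chi-square
#'   statistic, p-value, enriched strand and significance flag.
#' @export
strand_codon_chisq <- function(leading_counts, lagging_counts,
                               alpha = 0.001, bonferroni = FALSE) {
  tot <- function(x) if (is.null(dim(x))) x else colSums(x)
  lead <- tot(leading_counts)
  lag <- tot(lagging_counts)
  if (sum(lead) == 0 || sum(lag) == 0)
    stop("both strand classes must contain codons")
  rows <- list()
  for (fam in .SYN_FAMILIES) {
    fam_lead <- sum(lead[fam]); fam_lag <- sum(lag[fam])
    if (fam_lead + fam_lag == 0) next
    for (cod in fam) {
      a <- lead[[cod]]; b <- fam_lead - a
      cc <- lag[[cod]]; d <- fam_lag - cc
      tab <- matrix(c(a, b, cc, d), 2L, byrow = TRUE)
      n <- sum(tab)
      if (n == 0 || fam_lead == 0 || fam_lag == 0 ||
          (a + cc) == 0 || (b + d) == 0) next
      expected <- outer(rowSums(tab), colSums(tab)) / n
      chi <- n * (a * d - b * cc)^2 /
        (fam_lead * fam_lag * (a + cc) * (b + d))
      p <- if (any(expected < 5)) stats::fisher.test(tab)$p.value else
        stats::pchisq(chi, df = 1L, lower.tail = FALSE)
      enriched <- if (a / fam_lead > cc / fam_lag) "leading" else "lagging"
      rows[[length(rows) + 1L]] <- data.frame(
        codon = cod, amino_acid = unname(.GENETIC_CODE[cod]),
        leading = a, lagging = cc,
        leading_family = fam_lead, lagging_family = fam_lag,
        chisq = chi, p_value = p, enriched = enriched,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable codon families")
  thr <- if (bonferroni) alpha / nrow(out) else alpha
  out$significant <- out$p_value < thr
  rownames(out) <- NULL
  out
}
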