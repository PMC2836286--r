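.aa_count_vector <- function(proteins) {
  r <- unlist(strsplit(toupper(paste(proteins, collapse = "")), ""))
  tab <- table(factor(r, levels = .AA20))
  stats::setNames(as.integer(tab), .AA20)
}

#' Amino-acid usage of a protein set
#'
#' Relative frequencies of the 20 canonical residues over a proteome (or a
#' single protein). Nonstandard residues (X, B, Z, U, ...) are excluded
#' from both numerator and denominator.
#'
#' @param proteins character vector of amino-acid strings.
#' @return named numeric vector of 20 frequencies summing to 1, with the
#'   total canonical residue count in attribute \code{residues}.
#' @export
amino_acid_usage <- function(proteins) {
  if (length(proteins) == 0L || all(nchar(proteins) == 0L))
    stop("no protein sequences supplied")
  counts <- .aa_count_vector(proteins)
  tot <- sum(counts)
  if (tot == 0L) stop("no canonical residues in input")
  out <- counts / tot
  attr(out, "residues") <- tot
  out
}

#' Standardize amino-acid usage against a reference proteome
#'
#' Each residue's frequency is divided by its frequency in the reference
#' proteome, so the reference maps to 1 for every residue and values above
#' (below) 1 mark over- (under-) representation. A z-score variant
#' (difference scaled by the reference frequency's binomial SD) is
#' available for sensitivity analyses.
#'
#' @param org_usage,ref_usage frequency vectors from
#'   \code{\link{amino_acid_usage}}.
#' @param method \code{"ratio"} (default) or \code{"zscore"}.
#' @return named numeric vector of 20 standardized values.
#' @export
standardize_usage <- function(org_usage, ref_usage, method = c("ratio", "zscore")) {
  method <- match.arg(method)
  stopifnot(all(.AA20 %in% names(org_usage)), all(.AA20 %in% names(ref_usage)))
  o <- org_usage[.AA20]; rf <- ref_usage[.AA20]
  if (any(rf == 0)) stop("reference usage contains zero frequencies")
  if (method == "ratio") return(o / rf)
  n <- attr(org_usage, "residues") %||% 1e4
  (o - rf) / sqrt(rf * (1 - rf) / n)
}

#' Cluster organisms by standardized amino-acid usage
#'
#' Single-linkage agglomerative clustering on Euclidean distances between
#' the 20-dimensional standardized-usage vectors, with the heatmap matrix
#' (organisms x residues) and per-cell over/normal/under classes relative
#' to the neutral value (1 for ratio standardization, 0 for z-scores).
#'
#' @param usage_list named list of standardized usage vectors (one per
#'   organism; names must be unique).
#' @param neutral neutral value of the standardization (default 1).
#' @param band half-width of the "normal" band around neutral (default 0.1).
#' @return list with \code{tree} (an \code{hclust}), \code{matrix}
#'   (organisms x 20) and \code{classes} (character matrix).
#' @export
cluster_usage <- function(usage_list, neutral = 1, band = 0.1) {
  if (length(usage_list) < 2L) stop("need at least two organisms")
  ids <- names(usage_list)
  if (is.null(ids) || anyDuplicated(ids))
    stop("usage_list must have unique organism names")
  m <- do.call(rbind, lapply(usage_list, function(u) unname(u[.AA20])))
  dimnames(m) <- list(ids, .AA20)
  tree <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "single")
  classes <- matrix(ifelse(m > neutral + band, "over",
                           ifelse(m < neutral - band, "under", "normal")),
                    nrow(m), dimnames = dimnames(m))
  list(tree = tree, matrix = m, classes = classes)
}

.clean_protein <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1]]
  aa[aa %in% .AA20]
}

#' GRAVY score (grand average of hydropathy)
#'
#' Mean Kyte-Doolittle hydropathy over the canonical residues of a protein.
#'
#' @param protein amino-acid string.
#' @return numeric in [-4.5, 4.5].
#' @export
gravy <- function(protein) {
  aa <- .clean_protein(protein)
  if (length(aa) == 0L) stop("no canonical residues")
  mean(.KD[aa])
}

#' Aromaticity
#'
#' Fraction of residues that are Phe, Tyr or Trp.
#'
#' @param protein amino-acid string.
#' @return numeric in [0, 1].
#' @export
aromaticity <- function(protein) {
  aa <- .clean_protein(protein)
  if (length(aa) == 0L) stop("no canonical residues")
  mean(aa %in% c("F", "Y", "W"))
}

# net charge of a peptide at a given pH under the Bjellqvist pKa set
.net_charge <- function(pH, aa) {
  nterm_pk <- .PKA_NTERM[aa[1L]]
  if (is.na(nterm_pk)) nterm_pk <- .PKA_NTERM_DEFAULT
  pos_pk <- c(nterm_pk, .PKA_POS_SIDE[aa[aa %in% names(.PKA_POS_SIDE)]])
  neg_pk <- c(.PKA_CTERM, .PKA_NEG_SIDE[aa[aa %in% names(.PKA_NEG_SIDE)]])
  sum(1 / (1 + 10^(pH - pos_pk))) - sum(1 / (1 + 10^(neg_pk - pH)))
}

#' Isoelectric point
#'
#' pH at which the peptide's net charge is zero, found by bisection on
#' [0, 14] (the charge function is monotone decreasing in pH). Uses the
#' Bjellqvist pKa set as implemented by the ExPASy tools: side chains
#' D 4.05, E 4.45, H 5.98, C 9.0, Y 10.0, K 10.0, R 12.0; C-terminus 3.55;
#' N-terminus residue-dependent (default 7.5).
#'
#' @param protein amino-acid string.
#' @param tol convergence tolerance on |net charge| (default 1e-4).
#' @return pH in (0, 14).
#' @export
isoelectric_point <- function(protein, tol = 1e-4) {
  aa <- .clean_protein(protein)
  if (length(aa) == 0L) stop("no canonical residues")
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- .net_charge(mid, aa)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Instability index
#'
#' Guruprasad dipeptide-weight statistic: II = (10/L) * sum of DIWV weights
#' over consecutive residue pairs. Values above 40 conventionally predict
#' an unstable protein. Dipeptides containing a nonstandard residue
#' contribute the neutral weight 1.
#'
#' @param protein amino-acid string (length >= 2).
#' @return numeric instability index.
#' @export
instability_index <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1]]
  L <- length(aa)
  if (L < 2L) stop("instability index needs length >= 2")
  w <- vapply(seq_len(L - 1L), function(i) {
    a <- aa[i]; b <- aa[i + 1L]
    if (a %in% .AA20 && b %in% .AA20) .DIWV[a, b] else 1
  }, 0)
  10 / L * sum(w)
}

#' Three-state secondary-structure fractions (propensity heuristic)
#'
#' A deliberately simple propensity-based summary: per-residue Chou-Fasman
#' helix and sheet propensities are smoothed with a centered window of 5,
#' and each residue is assigned the state with the highest smoothed
#' propensity, against a coil baseline of 1. This is a fast compositional
#' heuristic for comparing proteome-level structural tendencies, not a
#' structure predictor; only orderings between proteomes should be
#' interpreted.
#'
#' @param protein amino-acid string (length >= 5).
#' @param window smoothing window (odd, default 5).
#' @return named numeric vector \code{c(helix, sheet, coil)} of percentages
#'   summing to 100.
#' @export
ss_fractions <- function(protein, window = 5L) {
  aa <- strsplit(toupper(protein), "")[[1]]
  if (length(aa) < 5L) stop("secondary-structure summary needs length >= 5")
  h <- ifelse(aa %in% .AA20, .CF_HELIX[aa], 1)
  s <- ifelse(aa %in% .AA20, .CF_SHEET[aa], 1)
  half <- (window - 1L) %/% 2L
  smooth <- function(x) {
    n <- length(x)
    vapply(seq_len(n), function(i)
      mean(x[max(1L, i - half):min(n, i + half)]), 0)
  }
  hs <- smooth(h); ss <- smooth(s)
  state <- ifelse(hs >= ss & hs > 1, "helix",
                  ifelse(ss > hs & ss > 1, "sheet", "coil"))
  100 * c(helix = mean(state == "helix"),
          sheet = mean(state == "sheet"),
          coil = mean(state == "coil"))
}

#' Per-protein index table
#'
#' Convenience wrapper computing all physicochemical and structural indices
#' for a set of proteins.
#'
#' @param proteins character vector (optionally named) of amino-acid strings.
#' @return data.frame with columns \code{protein_id, length, gravy,
#'   aromaticity, pI, instability, helix_pct, sheet_pct, coil_pct}.
#' @export
protein_indices <- function(proteins) {
  ids <- names(proteins) %||% as.character(seq_along(proteins))
  rows <- lapply(seq_along(proteins), function(i) {
    p <- proteins[[i]]
    ssf <- if (nchar(p) >= 5L) ss_fractions(p) else
      c(helix = NA_real_, sheet = NA_real_, coil = NA_real_)
    data.frame(protein_id = ids[i], length = nchar(p),
               gravy = gravy(p), aromaticity = aromaticity(p),
               pI = isoelectric_point(p),
               instability = if (nchar(p) >= 2L) instability_index(p) else NA_real_,
               helix_pct = ssf[["helix"]], sheet_pct = ssf[["sheet"]],
               coil_pct = ssf[["coil"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
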