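#' Symmetrized dinucleotide relative-abundance profile
#'
#' Computes the genome-signature odds ratios rho*_XY = f*_XY / (f*_X f*_Y)
#' on the strand-symmetrized sequence: dinucleotide and mononucleotide
#' frequencies are pooled over the sequence and its reverse complement,
#' counted separately (no dinucleotide is formed across the junction
#' between the two copies). On a circular genome the wrap dinucleotide
#' joining the last and first base is included within each strand copy.
#' Dinucleotides involving N are skipped. Values at or beyond 1.23 / 0.78
#' are conventionally called significantly over- / under-represented.
#'
#' @param x a \code{genome_record}, or a plain nucleotide string (treated
#'   as linear).
#' @param over,under classification cutoffs (defaults 1.23 and 0.78,
#'   inclusive).
#' @return object of class \code{dinucleotide_profile}: data.frame with one
#'   row per dinucleotide: \code{dinucleotide, rho, class}; symmetrization
#'   makes complementary pairs (e.g. CA and TG) exactly equal.
#' @export
dinucleotide_abundance <- function(x, over = 1.23, under = 0.78) {
  if (inherits(x, "genome_record")) {
    seqstr <- x$sequence
    circular <- x$topology == "circular"
  } else {
    seqstr <- toupper(x)
    circular <- FALSE
  }
  if (nchar(seqstr) == 0L) stop("empty sequence")
  if (nchar(seqstr) < 1000L)
    warning("sequence shorter than 1 kb: abundance estimates will be noisy")
  count_copy <- function(s) {
    ds <- Biostrings::DNAString(s)
    di <- Biostrings::dinucleotideFrequency(ds, step = 1L)
    mono <- Biostrings::letterFrequency(ds, letters = c("A", "C", "G", "T"))
    if (circular && nchar(s) >= 2L) {
      wrap <- paste0(substr(s, nchar(s), nchar(s)), substr(s, 1L, 1L))
      if (!grepl("[^ACGT]", wrap)) di[wrap] <- di[wrap] + 1L
    }
    list(di = di, mono = mono)
  }
  fwd <- count_copy(seqstr)
  rev <- count_copy(revcomp(seqstr))
  di <- fwd$di + rev$di
  mono <- fwd$mono + rev$mono
  if (sum(mono) == 0) stop("sequence contains no A/C/G/T bases")
  f_di <- di / sum(di)
  f_mono <- mono / sum(mono)
  dinucs <- names(di)
  rho <- vapply(dinucs, function(d) {
    b1 <- substr(d, 1L, 1L); b2 <- substr(d, 2L, 2L)
    denom <- f_mono[[b1]] * f_mono[[b2]]
    if (denom == 0) NA_real_ else f_di[[d]] / denom
  }, 0)
  cls <- ifelse(is.na(rho), NA_character_,
                ifelse(rho >= over, "over",
                       ifelse(rho <= under, "under", "normal")))
  out <- data.frame(dinucleotide = dinucs, rho = unname(rho),
                    class = unname(cls), stringsAsFactors = FALSE)
  class(out) <- c("dinucleotide_profile", "data.frame")
  out
}

#' Dinucleotide profile table for a panel of genomes
#'
#' Long-format table of rho* values and over/under classification for each
#' genome, ready for profile-line plotting, plus optional per-group summary
#' (mean and SD per dinucleotide) when a grouping is supplied.
#'
#' @param panels list of lists with a \code{genome} element, or a list of
#'   \code{genome_record}s.
#' @param groups optional character vector of group labels, one per genome.
#' @param over,under classification cutoffs.
#' @return list with \code{profiles} (long data.frame: genome, dinucleotide,
#'   rho, class, group) and \code{group_summary} (NULL without groups).
#' @export
profile_table <- function(panels, groups = NULL, over = 1.23, under = 0.78) {
  recs <- lapply(panels, function(p)
    if (inherits(p, "genome_record")) p else p$genome)
  rows <- lapply(seq_along(recs), function(i) {
    prof <- dinucleotide_abundance(recs[[i]], over = over, under = under)
    prof$genome <- recs[[i]]$id
    prof$group <- if (is.null(groups)) NA_character_ else groups[i]
    prof[, c("genome", "group", "dinucleotide", "rho", "class")]
  })
  profiles <- do.call(rbind, rows)
  group_summary <- NULL
  if (!is.null(groups)) {
    group_summary <- do.call(rbind, lapply(
      split(profiles, list(profiles$group, profiles$dinucleotide)),
      function(d) data.frame(group = d$group[1L],
                             dinucleotide = d$dinucleotide[1L],
                             mean_rho = mean(d$rho), sd_rho = stats::sd(d$rho),
                             stringsAsFactors = FALSE)))
    rownames(group_summary) <- NULL
  }
  list(profiles = profiles, group_summary = group_summary)
}
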