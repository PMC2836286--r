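# Internal lookup tables: genetic code machinery, published amino-acid scales,
# and motif constants. All constants are package-internal (not exported).

.BASES <- c("A", "C", "G", "T")

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# 64 codons in A/C/G/T nested order
.CODONS <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
.CODONS <- sort(.CODONS)

# Standard genetic code; identical to the bacterial/plastid code (table 11)
# for amino-acid assignments (table 11 differs only in permitted initiators).
.GENETIC_CODE <- Biostrings::GENETIC_CODE[.CODONS]

.STOP_CODONS <- names(.GENETIC_CODE)[.GENETIC_CODE == "*"]
.SENSE_CODONS <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]

# Initiator codons of the bacterial code; first codon of a CDS translates to M.
.START_CODONS <- c("ATG", "GTG", "TTG", "ATT", "CTG")

# Synonymous families (size >= 2): the 59 codons entering RSCU / GC3s / GT3s.
.FAMILIES <- split(.SENSE_CODONS, .GENETIC_CODE[.SENSE_CODONS])
.SYN_FAMILIES <- .FAMILIES[vapply(.FAMILIES, length, 1L) >= 2L]
.SYN_CODONS <- unname(unlist(.SYN_FAMILIES))

# DnaA box 9-mer consensus (E. coli-type)
.DNAA_BOX <- "TTATCCACA"

# Kyte-Doolittle hydropathy scale
.KD <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
         I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
         R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# Bjellqvist/ExPASy pKa values used for isoelectric-point bisection.
# Side chains, termini, and residue-specific N-terminal values.
.PKA_POS_SIDE <- c(H = 5.98, K = 10.0, R = 12.0)
.PKA_NEG_SIDE <- c(C = 9.0, D = 4.05, E = 4.45, Y = 10.0)
.PKA_CTERM <- 3.55
.PKA_NTERM_DEFAULT <- 7.5
.PKA_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
                E = 7.70)

# Chou-Fasman helix and sheet conformational propensities (classic table).
.CF_HELIX <- c(A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13, G = 0.57,
               H = 1.00, I = 1.08, K = 1.16, L = 1.21, M = 1.45, N = 0.67,
               P = 0.57, Q = 1.11, R = 0.98, S = 0.77, T = 0.83, V = 1.06,
               W = 1.08, Y = 0.69)
.CF_SHEET <- c(A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38, G = 0.75,
               H = 0.87, I = 1.60, K = 0.74, L = 1.30, M = 1.05, N = 0.89,
               P = 0.55, Q = 1.10, R = 0.93, S = 0.75, T = 1.19, V = 1.70,
               W = 1.37, Y = 1.47)

# Guruprasad dipeptide instability weight values (DIWV); rows index the first
# residue of the dipeptide, columns the second.
.DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE,
  dimnames = list(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
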