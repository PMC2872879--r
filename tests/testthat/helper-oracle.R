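# Independent naive-scan oracle for motif matching, built on base-R regular
# expressions (so it shares no code with the suffix-array path), plus small
# random fixture generators used across the suite.

ORACLE_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                    W = "AT", S = "CG", R = "AG", Y = "CT",
                    K = "GT", M = "AC", N = "ACGTN")

oracle_regex <- function(motif) {
  paste(vapply(strsplit(motif, "")[[1]],
               function(s) paste0("[", ORACLE_SETS[[s]], "]"), character(1)),
        collapse = "")
}

oracle_rc <- function(motif) {
  chartr("ACGTRYKM", "TGCAYRMK",
         paste(rev(strsplit(motif, "")[[1]]), collapse = ""))
}

# all 0-based match start offsets on the forward text (overlaps included)
oracle_starts <- function(motif, seq) {
  m <- gregexpr(paste0("(?=", oracle_regex(motif), ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

oracle_contains <- function(motif, seq, mode = "dna") {
  if (length(oracle_starts(motif, seq))) return(TRUE)
  if (mode == "dna") length(oracle_starts(oracle_rc(motif), seq)) > 0 else FALSE
}

oracle_positive_set <- function(motif, seqs, mode = "dna") {
  names(seqs)[vapply(seqs, oracle_contains, logical(1), motif = motif,
                     mode = mode)]
}

# brute-force enrichment score, written independently of the package path
oracle_enrichment <- function(e, pos_idx) {
  d <- length(e)
  n <- length(pos_idx)
  sigma <- sqrt(sum((e - mean(e))^2) / d)
  if (sigma == 0 || n == d) return(0)
  sqrt(n) * (mean(e[pos_idx]) - mean(e)) / sigma
}

random_region_seqs <- function(n, len, prefix = "r") {
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0(prefix, seq_len(n))
  seqs
}

random_motif <- function(min_len = 5, max_len = 8, degenerate = TRUE) {
  len <- sample(min_len:max_len, 1)
  syms <- if (degenerate) c("A", "C", "G", "T", "A", "C", "G", "T",
                            "W", "S", "R", "Y", "K", "M")
          else c("A", "C", "G", "T")
  m <- sample(syms, len, replace = TRUE)
  # interior positions may be N-degenerate in evolved motifs
  if (degenerate && len > 2 && runif(1) < 0.2)
    m[sample(2:(len - 1), 1)] <- "N"
  paste(m, collapse = "")
}

random_pssm <- function(w) {
  mat <- matrix(rexp(4 * w), nrow = 4)
  pssm(sweep(mat, 2, colSums(mat), "/"))
}
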