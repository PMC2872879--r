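# IUPAC motif algebra: the search space is the set of fixed-length strings
# over the 11-symbol degenerate alphabet {A,C,G,T,W,K,R,Y,S,M,N}.

IUPAC_SYMBOLS <- c("A", "C", "G", "T", "W", "K", "R", "Y", "S", "M", "N")

# base sets: which non-degenerate bases each symbol stands for
IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"), S = c("C", "G"), R = c("A", "G"),
  Y = c("C", "T"), K = c("G", "T"), M = c("A", "C"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  W = "W", S = "S", R = "Y", Y = "R", K = "M", M = "K", N = "N"
)

#' Validate an IUPAC motif string
#'
#' Checks that a motif is a single string over the 11-symbol degenerate
#' nucleotide alphabet `A C G T W K R Y S M N`.
#'
#' @param motif Character scalar.
#' @param min_len,max_len Permitted length range (the search operates on
#'   motifs of length 5 to 20).
#' @return `motif`, invisibly, upper-cased; errors otherwise.
#' @export
check_motif <- function(motif, min_len = 1L, max_len = 100L) {
  if (!is.character(motif) || length(motif) != 1L || is.na(motif))
    stop("motif must be a single character string")
  motif <- toupper(motif)
  sym <- strsplit(motif, "", fixed = TRUE)[[1]]
  bad <- which(!sym %in% IUPAC_SYMBOLS)
  if (length(bad))
    stop(sprintf("unknown IUPAC symbol '%s' at position %d", sym[bad[1]], bad[1]))
  if (length(sym) < min_len || length(sym) > max_len)
    stop(sprintf("motif length %d outside [%d, %d]", length(sym), min_len, max_len))
  invisible(motif)
}

#' Reverse complement of an IUPAC motif
#'
#' IUPAC-aware complement (A<->T, C<->G, R<->Y, K<->M; W, S, N self) followed
#' by reversal.  An involution: applying it twice returns the input.
#'
#' @param motif IUPAC motif string.
#' @return The reverse-complement motif string.
#' @examples
#' motif_revcomp("ACGTT")  # "AACGT"
#' motif_revcomp("RCATTC") # "GAATGY"
#' @export
motif_revcomp <- function(motif) {
  motif <- check_motif(motif)
  sym <- strsplit(motif, "", fixed = TRUE)[[1]]
  paste(rev(unname(IUPAC_COMPLEMENT[sym])), collapse = "")
}

#' Expand a degenerate motif into its exact instantiations
#'
#' Returns the Cartesian product of the per-position base sets; the number of
#' words equals the product of the per-symbol degeneracies.
#'
#' @param motif IUPAC motif string.
#' @return Character vector of non-degenerate words.
#' @examples
#' motif_expand("WCGTT") # "ACGTT" "TCGTT"
#' @export
motif_expand <- function(motif) {
  motif <- check_motif(motif)
  sym <- strsplit(motif, "", fixed = TRUE)[[1]]
  words <- ""
  for (s in sym) {
    bases <- IUPAC_BASES[[s]]
    words <- as.vector(outer(words, bases, paste0))
  }
  sort(words)
}

# regex character class for one motif: sequence N is matched only by motif N
.motif_regex <- function(motif) {
  sym <- strsplit(motif, "", fixed = TRUE)[[1]]
  cls <- vapply(sym, function(s) {
    b <- IUPAC_BASES[[s]]
    if (s == "N") b <- c(b, "N")
    if (length(b) == 1L) b else paste0("[", paste(b, collapse = ""), "]")
  }, character(1))
  paste(cls, collapse = "")
}

#' Test whether a motif occurs in a sequence
#'
#' A motif is present if some window of the sequence matches it
#' position-wise.  In `dna` mode either strand counts: the reverse
#' complement of the motif is also sought on the forward text.  In `rna`
#' mode only the forward strand is searched.  A sequence base `N` is matched
#' only by motif symbol `N`.
#'
#' @param motif IUPAC motif string.
#' @param seq Nucleotide string over `A C G T N` (`U` is normalised to `T`,
#'   case-insensitive).
#' @param mode `"dna"` (both strands) or `"rna"` (forward only).
#' @return Logical scalar; `FALSE` for an empty sequence.
#' @export
motif_matches <- function(motif, seq, mode = c("dna", "rna")) {
  mode <- match.arg(mode)
  motif <- check_motif(motif)
  seq <- normalize_sequence(seq)
  if (nchar(seq) < nchar(motif)) return(FALSE)
  if (grepl(.motif_regex(motif), seq)) return(TRUE)
  if (mode == "dna") grepl(.motif_regex(motif_revcomp(motif)), seq) else FALSE
}

#' Canonical form of a motif under reverse complementation
#'
#' The lexicographically smaller of a motif and its reverse complement, so
#' that a motif and its reverse complement (which define the same
#' double-stranded pattern) share one representative.  Pooling all 4^5
#' non-degenerate 5-mers this way yields 512 canonical seeds.
#'
#' @param motif IUPAC motif string.
#' @return Canonical motif string.
#' @export
motif_canonical <- function(motif) {
  motif <- check_motif(motif)
  rc <- motif_revcomp(motif)
  # plain C-locale comparison over the fixed symbol alphabet
  if (identical(sort(c(motif, rc), method = "radix")[1], rc)) rc else motif
}

#' Normalise an input nucleotide sequence
#'
#' Upper-cases, converts RNA `U` to `T`, and maps any residual non-`ACGT`
#' letter (including degenerate ambiguity codes) to `N`.  Soft-masked
#' (lowercase) bases are kept as their base by default; with
#' `mask_lower = TRUE` they become `N` so repeats cannot contribute matches.
#'
#' @param seq Character scalar.
#' @param mask_lower Treat lowercase input bases as `N`.
#' @return Normalised sequence over `A C G T N`.
#' @export
normalize_sequence <- function(seq, mask_lower = FALSE) {
  if (!is.character(seq) || length(seq) != 1L) stop("seq must be one string")
  if (mask_lower) seq <- gsub("[a-z]", "N", seq)
  seq <- toupper(seq)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  gsub("[^ACGT]", "N", seq)
}
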