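# Region sets and the suffix-array occurrence index.
#
# A region set holds the d putative regulatory regions S = {s_1, ..., s_d}
# (plus optional per-species ortholog sequences keyed by region id).  The
# index concatenates all sequences with sentinel separators, builds a suffix
# array over the text, and answers "which regions contain motif m" by
# branching binary-search descent over the degenerate symbols, so degenerate
# motifs are never expanded into literal word lists.

#' Construct a region set
#'
#' @param sequences Named character vector of nucleotide sequences; names are
#'   the unique region ids.
#' @param orthologs Optional named list: one element per species, each a
#'   named character vector of ortholog sequences keyed by primary region id
#'   (regions may be missing — no ortholog is then defined for them).
#' @param mask_lower Treat soft-masked (lowercase) bases as `N`.
#' @return An object of class `region_set` with elements `id`, `seq` and
#'   `orthologs`.
#' @export
region_set <- function(sequences, orthologs = NULL, mask_lower = FALSE) {
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("sequences must be named by region id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate region ids: ", paste(head(dup, 5), collapse = ", "))
  seqs <- vapply(sequences, normalize_sequence, character(1),
                 mask_lower = mask_lower)
  empty <- ids[nchar(seqs) == 0L]
  if (length(empty))
    stop("empty sequence for region: ", paste(head(empty, 5), collapse = ", "))
  orth <- list()
  if (!is.null(orthologs)) {
    if (is.null(names(orthologs))) stop("orthologs must be named by species")
    orth <- lapply(orthologs, function(x) {
      unknown <- setdiff(names(x), ids)
      if (length(unknown))
        stop("ortholog ids not in region set: ",
             paste(head(unknown, 5), collapse = ", "))
      vapply(x, normalize_sequence, character(1), mask_lower = mask_lower)
    })
  }
  structure(list(id = ids, seq = unname(seqs), orthologs = orth),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("Region set: %d regions, total %d nt",
              length(x$id), sum(nchar(x$seq))))
  if (length(x$orthologs))
    cat(sprintf("; orthologs for %d species (%s)",
                length(x$orthologs), paste(names(x$orthologs), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' @export
length.region_set <- function(x) length(x$id)

#' Read regions (and optional orthologs) from FASTA
#'
#' @param path FASTA file of primary regions; record ids must be unique.
#' @param ortholog_paths Optional named character vector of FASTA paths, one
#'   per species; record ids must be primary region ids (records for absent
#'   regions are an error, missing regions are allowed).
#' @param mask_lower Treat soft-masked bases as `N`.
#' @return A [region_set].
#' @export
read_regions <- function(path, ortholog_paths = NULL, mask_lower = FALSE) {
  fa <- Biostrings::readBStringSet(path)
  seqs <- as.character(fa)
  names(seqs) <- sub("\\s.*$", "", names(fa))
  orth <- NULL
  if (!is.null(ortholog_paths)) {
    if (is.null(names(ortholog_paths)))
      names(ortholog_paths) <- sub("\\.(fa|fasta|fna)$", "",
                                   basename(ortholog_paths))
    orth <- lapply(ortholog_paths, function(p) {
      o <- Biostrings::readBStringSet(p)
      os <- as.character(o)
      names(os) <- sub("\\s.*$", "", names(o))
      os
    })
  }
  region_set(seqs, orthologs = orth, mask_lower = mask_lower)
}

#' Build the suffix-array occurrence index for a region set
#'
#' @param regions A [region_set].
#' @return An object of class `motif_index` wrapping the compiled index; it
#'   also carries per-species ortholog indexes when the region set has
#'   orthologs, so conservation filtering can reuse the same query machinery.
#' @export
build_index <- function(regions) {
  stopifnot(inherits(regions, "region_set"))
  ptr <- .si_build(regions$seq)
  orth_idx <- lapply(regions$orthologs, function(x) {
    list(ptr = .si_build(unname(x)), id = names(x))
  })
  structure(list(ptr = ptr, id = regions$id, orthologs = orth_idx,
                 n_regions = length(regions$id)),
            class = "motif_index")
}

#' @export
print.motif_index <- function(x, ...) {
  cat(sprintf("Suffix-array motif index: %d regions, %d indexed positions\n",
              x$n_regions, .si_n_positions(x$ptr)))
  invisible(x)
}

# raw strand-aware query: list(fwd = int region idx, rev = int region idx)
.query_idx <- function(idx, motif, mode) {
  fwd <- .si_query_regions(idx$ptr, motif)
  rev <- integer(0)
  if (mode == "dna") {
    rc <- motif_revcomp(motif)
    rev <- if (identical(rc, motif)) fwd else .si_query_regions(idx$ptr, rc)
  }
  list(fwd = fwd, rev = rev)
}

#' Regions containing a motif
#'
#' The positive set of motif `m`: ids of all regions with at least one exact
#' match to the degenerate consensus, on either strand in `dna` mode or the
#' forward strand only in `rna` mode.
#'
#' @param idx A `motif_index` from [build_index()].
#' @param motif IUPAC motif string.
#' @param mode `"dna"` or `"rna"`.
#' @return Character vector of region ids (sorted in region-set order).
#' @export
regions_containing <- function(idx, motif, mode = c("dna", "rna")) {
  mode <- match.arg(mode)
  motif <- check_motif(motif)
  q <- .query_idx(idx, motif, mode)
  idx$id[sort(unique(c(q$fwd, q$rev)))]
}

# integer-index version used by the search inner loop
.containing_int <- function(idx, motif, mode) {
  q <- .query_idx(idx, motif, mode)
  sort(unique(c(q$fwd, q$rev)))
}

#' Occurrence positions of a motif
#'
#' All match windows per region, as 0-based start offsets with strand.  In
#' `dna` mode reverse-strand matches are windows on the forward text that
#' match the reverse complement of the motif; a reverse-complement-symmetric
#' motif is reported once per strand at the same offset.
#'
#' @inheritParams regions_containing
#' @return `data.frame` with columns `id`, `offset` (0-based), `strand`.
#' @export
occurrence_positions <- function(idx, motif, mode = c("dna", "rna")) {
  mode <- match.arg(mode)
  motif <- check_motif(motif)
  fwd <- .si_query_positions(idx$ptr, motif)
  out <- data.frame(id = idx$id[fwd$region], offset = fwd$offset,
                    strand = rep("+", nrow(fwd)), stringsAsFactors = FALSE)
  if (mode == "dna") {
    rev <- .si_query_positions(idx$ptr, motif_revcomp(motif))
    out <- rbind(out, data.frame(id = idx$id[rev$region], offset = rev$offset,
                                 strand = rep("-", nrow(rev)),
                                 stringsAsFactors = FALSE))
  }
  out[order(match(out$id, idx$id), out$offset, out$strand), , drop = FALSE]
}
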