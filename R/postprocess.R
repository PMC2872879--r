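# Post-processing of ranked motif predictions: PSSM construction from the
# exact occurrences in the positive set, a column-wise PSSM distance with an
# overlap-maximising similarity score, a hypergeometric co-occurrence test,
# and greedy peeling of the ranked list into clusters of redundant motifs.

BASES <- c("A", "C", "G", "T")

#' Construct a PSSM
#'
#' @param mat 4 x w numeric matrix (rows A, C, G, T) of column-stochastic
#'   base frequencies.
#' @param n_occurrences Number of aligned words the matrix was built from.
#' @return Object of class `pssm`.
#' @export
pssm <- function(mat, n_occurrences = NA_integer_) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PSSM must have 4 rows (A, C, G, T)")
  rownames(mat) <- BASES
  if (any(mat < 0)) stop("PSSM entries must be >= 0")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-9)) stop("PSSM columns must each sum to 1")
  structure(list(mat = mat, width = ncol(mat),
                 n_occurrences = n_occurrences), class = "pssm")
}

#' @export
print.pssm <- function(x, digits = 3, ...) {
  cat(sprintf("PSSM, width %d (%s occurrences), consensus %s\n", x$width,
              ifelse(is.na(x$n_occurrences), "?", x$n_occurrences),
              pssm_consensus(x)))
  print(round(x$mat, digits))
  invisible(x)
}

#' Majority-base consensus string of a PSSM
#' @param p A [pssm].
#' @return Character scalar.
#' @export
pssm_consensus <- function(p) {
  paste(BASES[apply(p$mat, 2, which.max)], collapse = "")
}

# reverse complement of a PSSM: reverse columns, swap A<->T and C<->G rows
.pssm_revcomp_mat <- function(mat) {
  mat[c("T", "G", "C", "A"), rev(seq_len(ncol(mat))), drop = FALSE]
}

#' Build the PSSM of a motif from its occurrences
#'
#' Every match window of the motif in its positive-set regions contributes
#' one aligned word (reverse-strand windows are reverse-complemented into
#' motif orientation); the matrix holds the per-column empirical base
#' frequencies.  Windows containing an `N` base are skipped.
#'
#' @param result A `motif_result` (from [greedy_evolve()]) or a list with
#'   elements `motif` and `positive`.
#' @param regions The [region_set] the result was computed on.
#' @param idx The `motif_index` over `regions`.
#' @param mode `"dna"` or `"rna"`.
#' @param pseudocount Per-base pseudocount added to the counts (default 0:
#'   pure empirical frequencies).
#' @return A [pssm].
#' @export
motif_pssm <- function(result, regions, idx, mode = c("dna", "rna"),
                       pseudocount = 0) {
  mode <- match.arg(mode)
  motif <- result$motif
  w <- nchar(motif)
  occ <- occurrence_positions(idx, motif, mode)
  occ <- occ[occ$id %in% result$positive, , drop = FALSE]
  if (!nrow(occ)) stop("no occurrences of ", motif, " in the positive set")
  seqs <- regions$seq[match(occ$id, regions$id)]
  words <- substr(seqs, occ$offset + 1L, occ$offset + w)
  rc <- occ$strand == "-"
  if (any(rc))
    words[rc] <- vapply(words[rc], motif_revcomp, character(1),
                        USE.NAMES = FALSE)
  words <- words[!grepl("N", words, fixed = TRUE)]
  if (!length(words)) stop("all occurrence windows contain N")
  counts <- matrix(pseudocount, nrow = 4, ncol = w, dimnames = list(BASES))
  chars <- matrix(unlist(strsplit(words, "", fixed = TRUE)),
                  nrow = w)  # columns = words
  for (i in seq_len(w)) {
    tab <- table(factor(chars[i, ], levels = BASES))
    counts[, i] <- counts[, i] + as.numeric(tab)
  }
  pssm(sweep(counts, 2, colSums(counts), "/"), n_occurrences = length(words))
}

#' Column-wise PSSM distance
#'
#' For equal-width PSSMs, the average over columns of the euclidean distance
#' between base-frequency columns scaled to the unit interval:
#' \deqn{D(a,b) = \frac{1}{w}\sum_{i=1}^{w}
#'   \sqrt{\tfrac{1}{2}\sum_{L}(a_{i,L}-b_{i,L})^2}.}
#' Symmetric, 0 for identical matrices, 1 for disjoint unit columns.
#'
#' @param p,q [pssm] objects of equal width.
#' @return Numeric distance in \[0, 1\].
#' @export
harbison_distance <- function(p, q) {
  if (p$width != q$width)
    stop("widths differ; use harbison_similarity for unequal widths")
  .mat_distance(p$mat, q$mat)
}

.mat_distance <- function(a, b) {
  mean(sqrt(0.5 * colSums((a - b)^2)))
}

#' Overlap-maximising PSSM similarity
#'
#' One minus the column distance, maximised over all overlap alignments of
#' the two PSSMs induced by shifts (and, in `dna` mode, over the reverse
#' complement orientation of the second PSSM), with minimum overlap six
#' columns — relaxed to five when either motif is only five wide.  Used with
#' a 0.75 cutoff to decide whether two predictions describe the same motif.
#'
#' @param p,q [pssm] objects (widths >= 5).
#' @param mode `"dna"` considers both orientations of `q`.
#' @param details Return the best alignment (shift/orientation) as
#'   attributes.
#' @return Similarity in \[0, 1\] (attributes `shift`, `orientation`,
#'   `overlap` when `details = TRUE`).
#' @export
harbison_similarity <- function(p, q, mode = c("dna", "rna"),
                                details = FALSE) {
  mode <- match.arg(mode)
  wp <- p$width; wq <- q$width
  min_overlap <- if (wp == 5L || wq == 5L) 5L else 6L
  orientations <- if (mode == "dna") c("+", "-") else "+"
  best <- -Inf; best_al <- NULL
  for (ori in orientations) {
    qm <- if (ori == "+") q$mat else .pssm_revcomp_mat(q$mat)
    # shift s: column i of p aligns with column i - s of q
    for (s in seq(-(wq - min_overlap), wp - min_overlap)) {
      lo <- max(1L, 1L + s); hi <- min(wp, wq + s)
      ov <- hi - lo + 1L
      if (ov < min_overlap) next
      sim <- 1 - .mat_distance(p$mat[, lo:hi, drop = FALSE],
                               qm[, (lo - s):(hi - s), drop = FALSE])
      if (sim > best) {
        best <- sim
        best_al <- list(shift = s, orientation = ori, overlap = ov)
      }
    }
  }
  if (details && !is.null(best_al)) {
    attr(best, "shift") <- best_al$shift
    attr(best, "orientation") <- best_al$orientation
    attr(best, "overlap") <- best_al$overlap
  }
  best
}

#' Hypergeometric co-occurrence P-value
#'
#' Upper-tail probability of observing at least `|cooccur|` regions in which
#' two motifs co-occur (both present, nearest occurrences within a distance
#' threshold) when positive sets of the observed sizes are drawn at random
#' from `d` regions.
#'
#' @param pos1,pos2 Character vectors: the two positive sets.
#' @param cooccur Character vector of co-occurring regions (must be a subset
#'   of both positive sets).
#' @param d Total number of regions.
#' @return P-value in (0, 1].
#' @export
cooccurrence_pvalue <- function(pos1, pos2, cooccur, d) {
  n1 <- length(pos1); n2 <- length(pos2); co <- length(cooccur)
  if (n1 > d || n2 > d) stop("positive sets larger than the region count")
  if (length(setdiff(cooccur, pos1)) || length(setdiff(cooccur, pos2)))
    stop("cooccur must be a subset of both positive sets")
  if (co == 0) return(1)
  phyper(co - 1, n2, d - n2, n1, lower.tail = FALSE)
}

# regions where both motifs occur with nearest start offsets within tau
.cooccurring_regions <- function(occ1, occ2, ids, tau) {
  both <- intersect(unique(occ1$id), unique(occ2$id))
  keep <- vapply(both, function(id) {
    o1 <- occ1$offset[occ1$id == id]
    o2 <- occ2$offset[occ2$id == id]
    min(abs(outer(o1, o2, "-"))) <= tau
  }, logical(1))
  both[keep]
}

#' Are two motif predictions redundant?
#'
#' Two predictions are similar when (1) their PSSMs have overlap similarity
#' of at least `sim_cutoff` and (2) the motifs co-occur in the same regions (nearest
#' occurrences within `tau` nucleotides) significantly more often than
#' chance (hypergeometric P <= `p_cutoff`).
#'
#' @param r1,r2 `motif_result` objects carrying `pssm` and `positive`.
#' @param idx The `motif_index`.
#' @param d Total region count.
#' @param mode `"dna"` or `"rna"`.
#' @param sim_cutoff Similarity cutoff (default 0.75).
#' @param tau Maximum nucleotide separation for co-occurrence (default 50).
#' @param p_cutoff Co-occurrence P-value threshold (default 0.05).
#' @return Logical.
#' @export
motifs_similar <- function(r1, r2, idx, d, mode = c("dna", "rna"),
                           sim_cutoff = 0.75, tau = 50, p_cutoff = 0.05) {
  mode <- match.arg(mode)
  if (harbison_similarity(r1$pssm, r2$pssm, mode) < sim_cutoff) return(FALSE)
  occ1 <- occurrence_positions(idx, r1$motif, mode)
  occ2 <- occurrence_positions(idx, r2$motif, mode)
  co <- .cooccurring_regions(occ1, occ2, idx$id, tau)
  co <- intersect(intersect(co, r1$positive), r2$positive)
  cooccurrence_pvalue(r1$positive, r2$positive, co, d) <= p_cutoff
}

#' Cluster a ranked list of motif predictions
#'
#' Greedy peeling: the highest-scoring remaining motif becomes the
#' representative of a new cluster; every remaining motif similar to it
#' (see [motifs_similar()]) joins the cluster and is removed; repeat until
#' no motifs remain.  Cluster indices increase as representative scores
#' decrease, and the clusters partition the input.
#'
#' @param results List of `motif_result` objects sorted by decreasing score,
#'   each carrying a `pssm`.
#' @param idx The `motif_index`.
#' @param mode `"dna"` or `"rna"`.
#' @param sim_cutoff,tau,p_cutoff See [motifs_similar()].
#' @return List of `motif_cluster` objects (`representative`, `members`,
#'   `pssm`).
#' @export
cluster_motifs <- function(results, idx, mode = c("dna", "rna"),
                           sim_cutoff = 0.75, tau = 50, p_cutoff = 0.05) {
  mode <- match.arg(mode)
  d <- idx$n_regions
  remaining <- results
  clusters <- list()
  while (length(remaining)) {
    rep <- remaining[[1]]
    remaining <- remaining[-1]
    sim <- vapply(remaining, function(r) {
      motifs_similar(rep, r, idx, d, mode, sim_cutoff, tau, p_cutoff)
    }, logical(1))
    cl <- structure(list(representative = rep,
                         members = remaining[sim], pssm = NULL),
                    class = "motif_cluster")
    cl$pssm <- cluster_pssm(cl, mode)
    clusters[[length(clusters) + 1L]] <- cl
    remaining <- remaining[!sim]
  }
  clusters
}

#' Score-weighted cluster PSSM
#'
#' Members are aligned into the representative's frame via the best
#' shift/orientation found by [harbison_similarity()]; each overlapping
#' column contributes the member's matrix weighted by its motif score
#' (negative scores floored at 0 with a warning), and columns are
#' renormalised to sum to 1.
#'
#' @param cluster A `motif_cluster`.
#' @param mode `"dna"` or `"rna"`.
#' @return A [pssm] of the representative's width.
#' @export
cluster_pssm <- function(cluster, mode = c("dna", "rna")) {
  mode <- match.arg(mode)
  rep <- cluster$representative
  wp <- rep$pssm$width
  acc <- matrix(0, 4, wp, dimnames = list(BASES))
  wt <- matrix(0, 4, wp)
  for (m in c(list(rep), cluster$members)) {
    w <- m$score
    if (w < 0) {
      warning("negative member score floored at 0 for ", m$motif)
      w <- 0
    }
    sim <- harbison_similarity(rep$pssm, m$pssm, mode, details = TRUE)
    s <- attr(sim, "shift"); ori <- attr(sim, "orientation")
    qm <- if (ori == "+") m$pssm$mat else .pssm_revcomp_mat(m$pssm$mat)
    lo <- max(1L, 1L + s); hi <- min(wp, m$pssm$width + s)
    acc[, lo:hi] <- acc[, lo:hi] + w * qm[, (lo - s):(hi - s), drop = FALSE]
    wt[, lo:hi] <- wt[, lo:hi] + w
  }
  avg <- ifelse(wt > 0, acc / wt, 0.25)  # uncovered columns: uniform
  pssm(sweep(avg, 2, colSums(avg), "/"),
       n_occurrences = rep$pssm$n_occurrences)
}
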