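# The search core: a gene-set-enrichment-style objective over the partition
# induced by a motif's positive set, local moves in motif space (extension,
# truncation, degeneracy), and a greedy hill climb from every non-degenerate
# 5-mer seed.

#' Search configuration
#'
#' @param mode `"dna"` (match both strands, pool reverse-complement seeds)
#'   or `"rna"` (forward strand only, all 4^5 seeds).
#' @param preset Named constraint preset: `"chip-chip"` sets the positive-set
#'   size bounds a = 20, b = 0.15 (used for ChIP-chip and over-expression
#'   data); `"chip-seq"` sets a = 100, b = 0.30.  `a` and `b` override the
#'   preset when given.
#' @param a Minimum positive-set size (inclusive).
#' @param b Maximum positive-set fraction of the region count (inclusive
#'   after flooring: n <= floor(b * d)).
#' @param conservation Refine positive sets by requiring the motif in all
#'   available ortholog sequences of each member region.
#' @param objective `"average"` scores the centred/scaled mean evidence of
#'   the positive set; `"selection"` first binarises evidence at threshold
#'   `k` (indicator e_j > k).
#' @param k Selection threshold for the `"selection"` objective, applied to
#'   the transformed evidence.
#' @param finite_population Apply the finite-population correction factor
#'   sqrt((d - n)/(d - 1)) in the score denominator.
#' @param min_len,max_len Motif length bounds for the move generators.
#' @param seed_length Length of the non-degenerate seed words (default 5).
#' @param evolve With `FALSE`, seeds are scored but not evolved (exhaustive
#'   fixed-length enumeration), a reduced search useful for calibration
#'   studies.
#' @return Object of class `search_config`.
#' @export
search_config <- function(mode = c("dna", "rna"),
                          preset = c("chip-chip", "chip-seq"),
                          a = NULL, b = NULL,
                          conservation = FALSE,
                          objective = c("average", "selection"), k = 0,
                          finite_population = FALSE,
                          min_len = 5L, max_len = 20L,
                          seed_length = 5L, evolve = TRUE) {
  mode <- match.arg(mode)
  preset <- match.arg(preset)
  objective <- match.arg(objective)
  if (is.null(a)) a <- if (preset == "chip-chip") 20L else 100L
  if (is.null(b)) b <- if (preset == "chip-chip") 0.15 else 0.30
  if (a < 1) stop("a must be >= 1")
  if (b <= 0 || b > 1) stop("b must be in (0, 1]")
  structure(list(mode = mode, preset = preset, a = as.integer(a), b = b,
                 conservation = conservation, objective = objective, k = k,
                 finite_population = finite_population,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 seed_length = as.integer(seed_length), evolve = evolve),
            class = "search_config")
}

#' Enrichment score of a positive set
#'
#' The objective function: the centred and scaled average evidence of the
#' positive set relative to a random set of the same size,
#' \deqn{J = \sqrt{n}\,\frac{\bar e^+ - \bar e}{\sigma_E},}
#' where n is the positive-set size, \eqn{\bar e^+} its mean evidence,
#' \eqn{\bar e} and \eqn{\sigma_E} the mean and population standard
#' deviation of the full evidence vector.  Invariant to positive affine
#' rescaling of the evidence.  Zero when the evidence is constant or the
#' positive set is the whole region set.
#'
#' @param evidence An [evidence_set] or numeric vector of evidence values.
#' @param positive_ids Region ids (or integer indices into `evidence`) of
#'   the positive set; must be non-empty and a subset of the regions.
#' @param finite_population Multiply the denominator by
#'   sqrt((d - n)/(d - 1)) (variance of a mean drawn without replacement).
#' @return Numeric score.
#' @export
enrichment_score <- function(evidence, positive_ids,
                             finite_population = FALSE) {
  e <- if (inherits(evidence, "evidence_set")) evidence$value else evidence
  idx <- if (is.numeric(positive_ids)) as.integer(positive_ids)
         else match(positive_ids, evidence$id)
  if (!length(idx) || anyNA(idx) || any(idx < 1L | idx > length(e)))
    stop("positive_ids must be a non-empty subset of the evidence regions")
  d <- length(e)
  stats <- .evidence_stats(e, finite_population)
  .score_sum(sum(e[idx]), length(idx), stats)
}

# precomputed global quantities reused across all per-motif score queries
.evidence_stats <- function(e, finite_population) {
  d <- length(e)
  mu <- mean(e)
  sigma <- sqrt(sum((e - mu)^2) / d)   # population sd
  list(d = d, mu = mu, sigma = sigma, fpc = finite_population)
}

# O(1) score from the positive-set evidence sum
.score_sum <- function(s, n, stats) {
  if (stats$sigma == 0 || n == stats$d) return(0)
  denom <- stats$sigma
  if (stats$fpc && stats$d > 1)
    denom <- denom * sqrt((stats$d - n) / (stats$d - 1))
  sqrt(n) * (s / n - stats$mu) / denom
}

#' Selection (thresholding) variant of the objective
#'
#' Applies [enrichment_score()] to the binarised evidence vector
#' `1(e_j > k)`: instead of averaging all evidence, only membership in the
#' top set above threshold `k` counts.  Zero when all indicators are equal.
#'
#' @inheritParams enrichment_score
#' @param k Threshold on the (transformed) evidence.
#' @return Numeric score.
#' @export
selection_score <- function(evidence, positive_ids, k,
                            finite_population = FALSE) {
  e <- if (inherits(evidence, "evidence_set")) evidence$value else evidence
  bin <- as.numeric(e > k)
  ev2 <- if (inherits(evidence, "evidence_set"))
    evidence_set(evidence$id, bin) else bin
  enrichment_score(ev2, positive_ids, finite_population)
}

#' Positive-set size constraint
#'
#' A positive set is admissible when a <= n <= floor(b * d): very small or
#' very large sets give unstable (high-variance) scores and are excluded
#' from the search.
#'
#' @param n Positive-set size.
#' @param d Total number of regions.
#' @param cfg A [search_config()].
#' @return Logical.
#' @export
size_constraint_ok <- function(n, d, cfg) {
  n >= cfg$a & n <= floor(cfg$b * d)
}

#' Extension moves
#'
#' Appends or prepends each of A, C, G, T to a motif, yielding eight
#' (k+1)-mers; no moves at the maximum length.
#'
#' @param motif IUPAC motif string.
#' @param max_len Length cap (default 20).
#' @return Character vector of candidate motifs.
#' @export
extension_moves <- function(motif, max_len = 20L) {
  motif <- check_motif(motif)
  if (nchar(motif) >= max_len) return(character(0))
  bases <- c("A", "C", "G", "T")
  c(paste0(bases, motif), paste0(motif, bases))
}

#' Truncation moves
#'
#' Drops the first or the last symbol, yielding two (k-1)-mers; only allowed
#' for motifs of length 6 or longer.
#'
#' @param motif IUPAC motif string.
#' @param min_len Shortest motif the search considers (default 5); truncation
#'   requires `nchar(motif) > min_len`.
#' @return Character vector of candidate motifs.
#' @export
truncation_moves <- function(motif, min_len = 5L) {
  motif <- check_motif(motif)
  w <- nchar(motif)
  if (w <= min_len || w < 6L) return(character(0))
  c(substr(motif, 2L, w), substr(motif, 1L, w - 1L))
}

# per-symbol degeneracy widening: base -> the three double-degenerate codes
# containing it; double-degenerate -> N (never at the terminal positions);
# N -> nothing
DEGENERACY_STEP <- list(
  A = c("M", "R", "W"), C = c("M", "S", "Y"),
  G = c("K", "R", "S"), T = c("K", "W", "Y"),
  R = "N", Y = "N", S = "N", M = "N", K = "N", W = "N",
  N = character(0)
)

#' Degeneracy moves
#'
#' One position is widened per candidate: a base becomes each of the three
#' double-degenerate codes that contain it (A -> M, R, W; C -> M, S, Y;
#' G -> K, R, S; T -> K, W, Y); a double-degenerate code becomes N, except
#' at the first and last positions; N is not updated.  A non-degenerate
#' k-mer therefore yields 3k candidates, a fully double-degenerate one
#' yields k - 2.
#'
#' @param motif IUPAC motif string.
#' @return Character vector of candidate motifs.
#' @export
degeneracy_moves <- function(motif) {
  motif <- check_motif(motif)
  sym <- strsplit(motif, "", fixed = TRUE)[[1]]
  w <- length(sym)
  out <- character(0)
  for (j in seq_len(w)) {
    repl <- DEGENERACY_STEP[[sym[j]]]
    if (identical(repl, "N") && (j == 1L || j == w)) next
    for (r in repl) {
      cand <- sym
      cand[j] <- r
      out <- c(out, paste(cand, collapse = ""))
    }
  }
  out
}

#' Full move neighbourhood of a motif
#'
#' Union of extension, truncation and degeneracy moves, de-duplicated, with
#' the motif itself excluded.
#'
#' @param motif IUPAC motif string.
#' @param cfg A [search_config()] (for the length bounds).
#' @return Character vector of candidate motifs.
#' @export
motif_neighborhood <- function(motif, cfg = search_config()) {
  out <- unique(c(extension_moves(motif, cfg$max_len),
                  truncation_moves(motif, cfg$min_len),
                  degeneracy_moves(motif)))
  setdiff(out, motif)
}

#' Enumerate the seed motifs
#'
#' All non-degenerate words of the seed length.  In `dna` mode a word and
#' its reverse complement define the same double-stranded pattern, so seeds
#' are pooled to their canonical forms: 512 seeds for 5-mers.  In `rna`
#' mode (forward-strand matching) all 4^5 = 1024 words are kept.
#'
#' @param cfg A [search_config()].
#' @return Character vector of seed motifs.
#' @export
enumerate_seeds <- function(cfg = search_config()) {
  words <- motif_expand(strrep("N", cfg$seed_length))
  if (cfg$mode == "dna") sort(unique(vapply(words, motif_canonical,
                                            character(1), USE.NAMES = FALSE)))
  else words
}

#' Conservation refinement of a positive set
#'
#' Regions stay in the positive set only if the motif also occurs in every
#' available ortholog sequence of the region; regions with no ortholog are
#' retained unconditionally, so datasets with partial ortholog coverage are
#' used in full.
#'
#' @param positive_ids Character vector of region ids containing the motif.
#' @param motif IUPAC motif string.
#' @param regions A [region_set] with (possibly empty) ortholog maps.
#' @param mode `"dna"` or `"rna"` (same matching semantics as the primary
#'   species).
#' @return Subset of `positive_ids`.
#' @export
conservation_refine <- function(positive_ids, motif, regions,
                                mode = c("dna", "rna")) {
  mode <- match.arg(mode)
  if (!length(regions$orthologs) || !length(positive_ids))
    return(positive_ids)
  keep <- rep(TRUE, length(positive_ids))
  for (sp in regions$orthologs) {
    present <- intersect(positive_ids, names(sp))
    if (!length(present)) next
    hit <- vapply(sp[present], function(s) motif_matches(motif, s, mode),
                  logical(1))
    drop <- present[!hit]
    keep[positive_ids %in% drop] <- FALSE
  }
  positive_ids[keep]
}

# index-backed refinement used in the search loop: ortholog indexes were
# built alongside the primary index
.refine_int <- function(pos_int, motif, idx, mode) {
  if (!length(idx$orthologs) || !length(pos_int)) return(pos_int)
  pos_ids <- idx$id[pos_int]
  keep <- rep(TRUE, length(pos_ids))
  for (sp in idx$orthologs) {
    q <- .query_idx(sp, motif, mode)
    hit_ids <- sp$id[sort(unique(c(q$fwd, q$rev)))]
    covered <- pos_ids %in% sp$id
    keep <- keep & (!covered | pos_ids %in% hit_ids)
  }
  pos_int[keep]
}

# motif -> refined positive set (integer indices), cached across the whole
# search (and across permutations: positive sets do not depend on evidence)
.positive_set_cached <- function(motif, idx, cfg, cache) {
  hit <- cache[[motif]]
  if (!is.null(hit)) return(hit)
  pos <- .containing_int(idx, motif, cfg$mode)
  if (cfg$conservation) pos <- .refine_int(pos, motif, idx, cfg$mode)
  cache[[motif]] <- pos
  pos
}

# score one motif given cached stats; NA when the size constraint fails
.score_motif <- function(motif, idx, stats, e, cfg, cache) {
  pos <- .positive_set_cached(motif, idx, cfg, cache)
  n <- length(pos)
  if (n < cfg$a || n > floor(cfg$b * stats$d)) return(NA_real_)
  .score_sum(sum(e[pos]), n, stats)
}

#' Greedily evolve one seed motif
#'
#' Hill climbing with strict improvement: at each step every candidate in
#' the move neighbourhood whose (conservation-refined) positive set
#' satisfies the size constraint is scored, and the best candidate is
#' adopted only if its score strictly exceeds the current score; exact ties
#' for the best candidate are broken by the lexicographically smallest motif
#' string, making the search fully deterministic.  A seed whose own positive
#' set violates the size constraint carries score `-Inf`, so the climb can
#' still enter the admissible window through the moves (short seeds are
#' ubiquitous in long regions, and extension shrinks their positive sets);
#' a trajectory that never reaches an admissible motif is invalid (returns
#' `NULL`).
#'
#' @param seed Seed motif (IUPAC string).
#' @param idx A `motif_index` over the regions.
#' @param evidence An [evidence_set] aligned with the index regions.
#' @param cfg A [search_config()].
#' @return A list (class `motif_result`) with elements `motif`, `score`,
#'   `n`, `positive`, `seed`, `steps`; or `NULL` for an invalid seed.
#' @export
greedy_evolve <- function(seed, idx, evidence, cfg = search_config()) {
  seed <- check_motif(seed)
  e <- .align_evidence(evidence, idx)
  stats <- .evidence_stats(e, cfg$finite_population)
  if (cfg$objective == "selection") {
    e <- as.numeric(e > cfg$k)
    stats <- .evidence_stats(e, cfg$finite_population)
  }
  cache <- new.env(parent = emptyenv())
  .evolve_one(seed, idx, stats, e, cfg, cache)
}

.evolve_one <- function(seed, idx, stats, e, cfg, cache) {
  # A seed whose own positive set lies outside [a, b*d] is not scoreable
  # (score -Inf); the climb may still enter the feasible window through the
  # moves (e.g. extension shrinks an over-populous set).  If it never does,
  # the seed is invalid and dropped.
  cur <- seed
  cur_score <- .score_motif(cur, idx, stats, e, cfg, cache)
  if (is.na(cur_score)) cur_score <- -Inf
  steps <- 0L
  if (cfg$evolve) {
    repeat {
      cand <- motif_neighborhood(cur, cfg)
      if (!length(cand)) break
      sc <- vapply(cand, .score_motif, numeric(1),
                   idx = idx, stats = stats, e = e, cfg = cfg, cache = cache,
                   USE.NAMES = FALSE)
      ok <- which(!is.na(sc))
      if (!length(ok)) break
      best <- max(sc[ok])
      if (!(best > cur_score)) break
      ties <- cand[ok][sc[ok] == best]
      cur <- sort(ties, method = "radix")[1]
      cur_score <- best
      steps <- steps + 1L
    }
  }
  if (!is.finite(cur_score)) return(NULL)
  pos <- .positive_set_cached(cur, idx, cfg, cache)
  structure(list(motif = cur, score = cur_score, n = length(pos),
                 positive = idx$id[pos], seed = seed, steps = steps),
            class = "motif_result")
}

# align an evidence_set (or named/plain numeric) with the index region order
.align_evidence <- function(evidence, idx) {
  if (inherits(evidence, "evidence_set")) {
    m <- match(idx$id, evidence$id)
    if (anyNA(m)) stop("evidence missing for ", sum(is.na(m)), " regions")
    evidence$value[m]
  } else if (!is.null(names(evidence))) {
    m <- match(idx$id, names(evidence))
    if (anyNA(m)) stop("evidence missing for ", sum(is.na(m)), " regions")
    unname(evidence[m])
  } else {
    if (length(evidence) != idx$n_regions)
      stop("evidence length does not match region count")
    as.numeric(evidence)
  }
}

# full search over all seeds; internal core shared by evimotif() and the
# permutation null.  Returns a list of motif_result, ranked.
.search_core <- function(idx, e, cfg, cache = NULL, top_m = Inf) {
  stats <- .evidence_stats(e, cfg$finite_population)
  if (cfg$objective == "selection") {
    e <- as.numeric(e > cfg$k)
    stats <- .evidence_stats(e, cfg$finite_population)
  }
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  seeds <- enumerate_seeds(cfg)
  results <- vector("list", length(seeds))
  for (i in seq_along(seeds))
    results[[i]] <- .evolve_one(seeds[i], idx, stats, e, cfg, cache)
  results <- results[!vapply(results, is.null, logical(1))]
  if (!length(results)) return(list())
  # canonicalize final motifs in dna mode so a motif and its reverse
  # complement (identical positive sets) merge into one entry
  if (cfg$mode == "dna")
    for (i in seq_along(results))
      results[[i]]$motif <- motif_canonical(results[[i]]$motif)
  motifs <- vapply(results, `[[`, character(1), "motif")
  scores <- vapply(results, `[[`, numeric(1), "score")
  ord <- order(-scores, motifs, method = "radix")
  results <- results[ord][!duplicated(motifs[ord])]
  if (is.finite(top_m) && length(results) > top_m)
    results <- results[seq_len(top_m)]
  results
}
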