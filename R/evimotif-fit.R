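# The main user-facing fit: run the full evidence-ranked motif search on a
# region set, post-process into PSSMs and clusters, and return one classed
# object.

#' Evidence-ranked motif discovery
#'
#' Runs the complete discovery procedure: every non-degenerate seed word is
#' greedily evolved (varying length and degeneracy) to maximise the
#' enrichment of its positive set in the region-level evidence; the evolved
#' motifs are ranked by score, de-duplicated, summarised as PSSMs from their
#' exact occurrences, and clustered into non-redundant predictions.
#'
#' @param regions A [region_set] (or a named character vector of sequences).
#' @param evidence An [evidence_set] (or a numeric vector named by region
#'   id) of per-region evidence of regulation.
#' @param cfg A [search_config()]; the convenience arguments below override
#'   its fields.
#' @param mode,preset,a,b,conservation,objective,k See [search_config()].
#' @param top_m Number of ranked motifs retained for post-processing
#'   (default 50).
#' @param cluster Cluster the ranked motifs (default `TRUE`).
#' @param sim_cutoff,tau,p_cutoff Clustering parameters; see
#'   [motifs_similar()].
#' @param pseudocount PSSM pseudocount (default 0).
#' @return An object of class `evimotif`: list with `motifs` (ranked
#'   `data.frame`), `results` (full `motif_result` list with PSSMs),
#'   `clusters`, `config`, `index`, `regions`, `evidence`, `call`.
#' @examples
#' sim <- synthesize_dataset(d = 150, region_length = 100,
#'                           motif = "TGACTCA", planted_fraction = 0.2,
#'                           effect = 3, noise_sd = 1, seed = 1)
#' fit <- evimotif(sim$regions, sim$evidence, a = 10, top_m = 10)
#' fit
#' @export
evimotif <- function(regions, evidence, cfg = NULL,
                     mode = "dna", preset = "chip-chip",
                     a = NULL, b = NULL, conservation = FALSE,
                     objective = "average", k = 0,
                     top_m = 50L, cluster = TRUE,
                     sim_cutoff = 0.75, tau = 50, p_cutoff = 0.05,
                     pseudocount = 0) {
  if (!inherits(regions, "region_set")) regions <- region_set(regions)
  if (is.null(cfg))
    cfg <- search_config(mode = mode, preset = preset, a = a, b = b,
                         conservation = conservation, objective = objective,
                         k = k)
  d <- length(regions$id)
  if (d < cfg$a)
    stop(sprintf(paste0("only %d regions but the minimum positive-set size ",
                        "is a = %d; lower `a` or provide more regions"),
                 d, cfg$a))
  if (!inherits(evidence, "evidence_set")) {
    if (is.null(names(evidence)) && length(evidence) == d)
      names(evidence) <- regions$id
    evidence <- evidence_set(names(evidence), unname(evidence))
  }
  idx <- build_index(regions)
  e <- .align_evidence(evidence, idx)
  results <- .search_core(idx, e, cfg, top_m = top_m)
  for (i in seq_along(results))
    results[[i]]$pssm <- motif_pssm(results[[i]], regions, idx,
                                    mode = cfg$mode,
                                    pseudocount = pseudocount)
  clusters <- if (cluster && length(results))
    cluster_motifs(results, idx, mode = cfg$mode, sim_cutoff = sim_cutoff,
                   tau = tau, p_cutoff = p_cutoff)
  else list()
  motifs <- if (length(results)) data.frame(
    rank = seq_along(results),
    motif = vapply(results, `[[`, character(1), "motif"),
    score = vapply(results, `[[`, numeric(1), "score"),
    n = vapply(results, `[[`, integer(1), "n"),
    seed = vapply(results, `[[`, character(1), "seed"),
    steps = vapply(results, `[[`, integer(1), "steps"),
    stringsAsFactors = FALSE
  ) else data.frame(rank = integer(), motif = character(),
                    score = numeric(), n = integer(),
                    seed = character(), steps = integer())
  structure(list(motifs = motifs, results = results, clusters = clusters,
                 config = cfg, index = idx, regions = regions,
                 evidence = evidence, d = d,
                 cluster_params = list(sim_cutoff = sim_cutoff, tau = tau,
                                       p_cutoff = p_cutoff),
                 call = match.call()),
            class = "evimotif")
}

#' @export
print.evimotif <- function(x, n = 5, ...) {
  cat(sprintf("Evidence-ranked motif search (%s mode, a = %d, b = %.2f)\n",
              x$config$mode, x$config$a, x$config$b))
  cat(sprintf("%d regions; %d ranked motifs in %d clusters\n\n",
              x$d, nrow(x$motifs), length(x$clusters)))
  if (nrow(x$motifs)) {
    print(head(x$motifs[c("rank", "motif", "score", "n")], n),
          row.names = FALSE)
    if (nrow(x$motifs) > n) cat("...\n")
  }
  invisible(x)
}

#' @export
summary.evimotif <- function(object, ...) {
  cl <- lapply(seq_along(object$clusters), function(i) {
    c0 <- object$clusters[[i]]
    data.frame(cluster = i,
               representative = c0$representative$motif,
               score = c0$representative$score,
               n_regions = c0$representative$n,
               members = length(c0$members) + 1L,
               consensus = pssm_consensus(c0$pssm),
               p_value = if (!is.null(c0$representative$p_value))
                 c0$representative$p_value else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- list(clusters = do.call(rbind, cl), motifs = object$motifs,
              config = object$config)
  class(out) <- "summary.evimotif"
  out
}

#' @export
print.summary.evimotif <- function(x, ...) {
  cat("Motif clusters (representative = highest-scoring member):\n")
  if (!is.null(x$clusters)) print(x$clusters, row.names = FALSE)
  else cat("  none\n")
  invisible(x)
}

#' @export
plot.evimotif <- function(x, top = 10, ...) {
  m <- head(x$motifs, top)
  if (!nrow(m)) {
    warning("no motifs to plot")
    return(invisible(x))
  }
  op <- graphics::par(mar = c(5, 7, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(m$score), names.arg = rev(m$motif), horiz = TRUE,
                    las = 1, xlab = "enrichment score J",
                    main = "Top ranked motifs", ...)
  invisible(x)
}

#' Attach permutation significance to a fit
#'
#' Builds the permutation null for the fit's configuration (see
#' [permutation_null()]) and annotates each ranked motif, and each cluster
#' representative, with its Gamma-tail P-value.
#'
#' @param fit An [evimotif] object.
#' @param n_perm Number of permutations (default 100).
#' @param seed RNG seed.
#' @return The fit with `null` attached, a `p_value` column in `$motifs`,
#'   and `p_value` set on each result and cluster representative.
#' @export
motif_significance <- function(fit, n_perm = 100L, seed = 1L) {
  stopifnot(inherits(fit, "evimotif"))
  null <- permutation_null(fit$index, fit$evidence, fit$config,
                           n_perm = n_perm, seed = seed)
  fit$null <- null
  if (nrow(fit$motifs))
    fit$motifs$p_value <- motif_pvalue(fit$motifs$score, null)
  for (i in seq_along(fit$results))
    fit$results[[i]]$p_value <- motif_pvalue(fit$results[[i]]$score, null)
  for (i in seq_along(fit$clusters))
    fit$clusters[[i]]$representative$p_value <-
      motif_pvalue(fit$clusters[[i]]$representative$score, null)
  fit
}

#' Canonical miRNA seed-match motifs
#'
#' The four canonical seed-match sites of a microRNA: the DNA reverse
#' complements of miRNA positions 2-7, 1-7, 2-8 and 1-8 (5' to 3'), to be
#' matched on the forward strand of 3' UTR regions.
#'
#' @param mirna miRNA sequence, 5' to 3' (RNA or DNA letters), length >= 8.
#' @return Named character vector of four DNA motifs (lengths 6, 7, 7, 8),
#'   names `"2-7"`, `"1-7"`, `"2-8"`, `"1-8"`.
#' @export
mirna_seed_motifs <- function(mirna) {
  if (!is.character(mirna) || length(mirna) != 1L)
    stop("mirna must be one string")
  s <- normalize_sequence(mirna)
  if (nchar(s) < 8L) stop("miRNA must be at least 8 nt long")
  ranges <- list("2-7" = c(2, 7), "1-7" = c(1, 7),
                 "2-8" = c(2, 8), "1-8" = c(1, 8))
  vapply(ranges, function(r) motif_revcomp(substr(s, r[1], r[2])),
         character(1))
}

#' Score the canonical miRNA seed matches
#'
#' Evaluates the same enrichment objective for each of the four canonical
#' seed-match motifs of a miRNA against a 3' UTR region set (forward-strand
#' matching), the baseline the full search is compared to.
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param idx A `motif_index` over the 3' UTR regions.
#' @param evidence An [evidence_set] (typically expression fold-change
#'   evidence).
#' @param cfg A [search_config()]; matching uses `rna` mode regardless.
#' @return `data.frame` with columns `seed`, `motif`, `n`, `score` (NA score
#'   when the positive set violates the size constraint), plus attribute
#'   `best` = max valid score.
#' @export
mirna_seed_scores <- function(mirna, idx, evidence, cfg = search_config()) {
  motifs <- mirna_seed_motifs(mirna)
  e <- .align_evidence(evidence, idx)
  stats <- .evidence_stats(e, cfg$finite_population)
  rows <- lapply(names(motifs), function(nm) {
    m <- motifs[[nm]]
    pos <- .containing_int_mode(idx, m, "rna")
    n <- length(pos)
    sc <- if (n >= cfg$a && n <= floor(cfg$b * stats$d) && n > 0)
      .score_sum(sum(e[pos]), n, stats) else NA_real_
    data.frame(seed = nm, motif = m, n = n, score = sc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- if (all(is.na(out$score))) NA_real_
                       else max(out$score, na.rm = TRUE)
  out
}

.containing_int_mode <- function(idx, motif, mode) {
  q <- .query_idx(idx, motif, mode)
  sort(unique(c(q$fwd, q$rev)))
}
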