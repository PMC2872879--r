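# Fixtures, evaluation helpers, and report / motif-format writers.

#' Synthesise a planted-motif dataset
#'
#' Generates d iid random regions; inserts one exact instantiation of the
#' planted IUPAC motif at a uniform position into ceil(planted_fraction * d)
#' of them; and draws evidence as `effect * planted + Normal(0, noise_sd)`,
#' emulating an experiment in which evidence of regulation is high for the
#' motif-carrying regions and background elsewhere.  Deterministic given
#' `seed`.
#'
#' @param d Number of regions (default 500).
#' @param region_length Region length in nt (default 200).
#' @param motif Planted IUPAC motif (default the AP-1 heptamer `TGACTCA`).
#' @param planted_fraction Fraction of regions receiving an insertion
#'   (default 0.1).
#' @param effect Evidence effect size Delta for planted regions (default 3).
#' @param noise_sd Evidence noise standard deviation (default 1).
#' @param base_comp Base composition of the background sequence (A, C, G,
#'   T; default uniform).
#' @param seed RNG seed.
#' @return List with `regions` ([region_set]), `evidence` ([evidence_set])
#'   and `truth` (list: `motif`, `planted_ids`, `positions`, `words`).
#' @export
synthesize_dataset <- function(d = 500L, region_length = 200L,
                               motif = "TGACTCA", planted_fraction = 0.1,
                               effect = 3, noise_sd = 1,
                               base_comp = c(0.25, 0.25, 0.25, 0.25),
                               seed = 1L) {
  motif <- check_motif(motif)
  w <- nchar(motif)
  if (w > region_length) stop("motif longer than the regions")
  if (planted_fraction <= 0 || planted_fraction >= 1)
    stop("planted_fraction must be in (0, 1)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  ids <- sprintf("region_%04d", seq_len(d))
  seqs <- vapply(seq_len(d), function(i) {
    paste(sample(c("A", "C", "G", "T"), region_length, replace = TRUE,
                 prob = base_comp), collapse = "")
  }, character(1))
  n_planted <- as.integer(ceiling(planted_fraction * d))
  planted <- sort(sample.int(d, n_planted))
  words <- motif_expand(motif)
  pos <- integer(n_planted)
  ins <- character(n_planted)
  for (j in seq_along(planted)) {
    i <- planted[j]
    word <- sample(words, 1L)
    p <- sample.int(region_length - w + 1L, 1L)  # 1-based insert position
    substr(seqs[i], p, p + w - 1L) <- word
    pos[j] <- p - 1L                             # report 0-based
    ins[j] <- word
  }
  e <- effect * as.numeric(seq_len(d) %in% planted) + rnorm(d, 0, noise_sd)
  list(regions = region_set(stats::setNames(seqs, ids)),
       evidence = evidence_set(ids, e, type = "raw"),
       truth = list(motif = motif, planted_ids = ids[planted],
                    positions = pos, words = ins))
}

#' True/false-positive rates as integer percents
#'
#' `tp_rate = round(100 * tp / (tp + fn))`, `fp_rate =
#' round(100 * fp / (fp + tn))`, rounded to the nearest integer with halves
#' away from zero.
#'
#' @param tp,fn,tn,fp Non-negative counts; `tp + fn` and `tn + fp` must be
#'   positive.
#' @return Named numeric vector `c(tp_rate, fp_rate)`.
#' @export
success_rates <- function(tp, fn, tn, fp) {
  if (any(c(tp, fn, tn, fp) < 0)) stop("counts must be non-negative")
  if (tp + fn == 0) stop("tp + fn must be positive")
  if (tn + fp == 0) stop("tn + fp must be positive")
  half_away <- function(x) floor(x + 0.5)
  c(tp_rate = half_away(100 * tp / (tp + fn)),
    fp_rate = half_away(100 * fp / (fp + tn)))
}

#' Did the predictions recover a known motif?
#'
#' `TRUE` when any of the first `top_n` predicted PSSMs matches the
#' literature PSSM at overlap similarity >= `cutoff` (see
#' [harbison_similarity()]).
#'
#' @param predictions List of [pssm] objects, ranked.
#' @param literature The reference [pssm].
#' @param cutoff Similarity cutoff (default 0.75).
#' @param top_n How many top predictions may count (default 1).
#' @param mode `"dna"` or `"rna"`.
#' @return Logical.
#' @export
evaluate_success <- function(predictions, literature, cutoff = 0.75,
                             top_n = 1L, mode = c("dna", "rna")) {
  mode <- match.arg(mode)
  if (!length(predictions)) stop("no predictions supplied")
  for (p in head(predictions, top_n))
    if (harbison_similarity(p, literature, mode) >= cutoff) return(TRUE)
  FALSE
}

#' Build a PSSM from a consensus string
#'
#' Unit columns for bases, uniform over the base set for degenerate
#' symbols; handy for literature consensus comparisons.
#'
#' @param motif IUPAC motif string.
#' @return A [pssm].
#' @export
consensus_pssm <- function(motif) {
  motif <- check_motif(motif)
  sym <- strsplit(motif, "", fixed = TRUE)[[1]]
  mat <- vapply(sym, function(s) {
    b <- IUPAC_BASES[[s]]
    col <- stats::setNames(numeric(4), BASES)
    col[b] <- 1 / length(b)
    col
  }, numeric(4))
  pssm(matrix(mat, nrow = 4, dimnames = list(BASES)))
}

#' Write regions to FASTA
#'
#' @param regions A [region_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(regions$seq, regions$id)), path)
  invisible(path)
}

#' Write an evidence set as two-column TSV
#'
#' Writes the raw values (the transform is re-applied on read).
#'
#' @param evidence An [evidence_set].
#' @param path Output path.
#' @param raw Write the raw column (default) or the transformed values.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(evidence, path, raw = TRUE) {
  val <- if (raw) evidence$raw else evidence$value
  write.table(data.frame(evidence$id, val), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write PSSMs in MEME minimal motif format
#'
#' @param pssms Named list of [pssm] objects (names become motif ids).
#' @param path Output path.
#' @param background Background base frequencies (default uniform).
#' @return `path`, invisibly.
#' @export
write_meme <- function(pssms, path, background = rep(0.25, 4)) {
  if (is.null(names(pssms))) names(pssms) <- sprintf("motif_%d",
                                                     seq_along(pssms))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background[1],
                       background[2], background[3], background[4]), ""),
             con)
  for (nm in names(pssms)) {
    p <- pssms[[nm]]
    nsites <- if (is.na(p$n_occurrences)) 20L else p$n_occurrences
    writeLines(c(sprintf("MOTIF %s", nm),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         p$width, nsites)), con)
    writeLines(apply(p$mat, 2, function(col)
      sprintf(" %.6f %.6f %.6f %.6f", col[1], col[2], col[3], col[4])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PSSMs from MEME minimal motif format
#'
#' @param path MEME file path.
#' @return Named list of [pssm] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF ", lines[i])) {
      nm <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1L
      while (j <= length(lines) && !grepl("letter-probability matrix",
                                          lines[j])) j <- j + 1L
      w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[j]))
      nsites <- if (grepl("nsites=", lines[j]))
        as.integer(sub(".*nsites= *(\\d+).*", "\\1", lines[j])) else NA_integer_
      rows <- lines[(j + 1L):(j + w)]
      mat <- vapply(rows, function(r)
        as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4),
        USE.NAMES = FALSE)                 # 4 x w, rows A C G T
      mat <- sweep(mat, 2, colSums(mat), "/")
      out[[nm]] <- pssm(mat, n_occurrences = nsites)
      i <- j + w
    }
    i <- i + 1L
  }
  out
}

#' Write the ranked-motif report
#'
#' TSV of the ranked motifs with a comment header recording the full
#' resolved configuration (reproducibility contract).
#'
#' @param fit An [evimotif] fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_report <- function(fit, path) {
  cfg <- fit$config
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    paste0("# evimotif report | mode=%s preset=%s a=%d b=%g conservation=%s ",
           "objective=%s k=%g finite_population=%s seed_length=%d evolve=%s ",
           "sim_cutoff=%g tau=%g p_cutoff=%g d=%d"),
    cfg$mode, cfg$preset, cfg$a, cfg$b, cfg$conservation, cfg$objective,
    cfg$k, cfg$finite_population, cfg$seed_length, cfg$evolve,
    fit$cluster_params$sim_cutoff, fit$cluster_params$tau,
    fit$cluster_params$p_cutoff, fit$d), con)
  m <- fit$motifs
  writeLines(paste(names(m), collapse = "\t"), con)
  write.table(m, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write the cluster report
#'
#' TSV: cluster id, representative motif, score, positive-set size,
#' P-value (if significance was attached), consensus of the cluster PSSM,
#' and member motifs.
#'
#' @param fit An [evimotif] fit with clusters.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(fit, path) {
  rows <- lapply(seq_along(fit$clusters), function(i) {
    cl <- fit$clusters[[i]]
    data.frame(cluster = i, representative = cl$representative$motif,
               score = cl$representative$score, n = cl$representative$n,
               p_value = if (!is.null(cl$representative$p_value))
                 cl$representative$p_value else NA_real_,
               consensus = pssm_consensus(cl$pssm),
               members = paste(vapply(cl$members, `[[`, character(1),
                                      "motif"), collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), representative = character(),
               score = numeric(), n = integer(), p_value = numeric(),
               consensus = character(), members = character())
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
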