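# ChIP-seq / open-chromatin preprocessing: read-level filters, peak width
# normalisation, ensemble region-set definition, and evidence assignment by
# peak overlap.  Coordinates are 0-based half-open throughout (BED
# convention).

#' Filter aligned reads
#'
#' Applies, in order: (1) keep reads mapping to at most four genomic
#' locations; (2) remove single-base pile-ups — wherever a 30-bp window
#' holds more than 10 reads of which at least 70% map to a single base
#' location, the reads at that base are removed; (3) at locations with more
#' than five remaining tags, trim the tag count to five.
#'
#' @param alignments `data.frame` with columns `read_id`, `chrom`, `pos`
#'   (0-based), `strand`, `n_hits`; must be coordinate-sorted within each
#'   chromosome.
#' @param window Pile-up window width in bp (default 30).
#' @param pileup_min_reads Window read count that triggers the pile-up test
#'   (strictly more than this; default 10).
#' @param pileup_fraction Dominant-base fraction (default 0.7).
#' @param max_tags Per-location tag cap (default 5).
#' @return Filtered `data.frame`, same columns.
#' @export
filter_alignments <- function(alignments, window = 30L,
                              pileup_min_reads = 10L, pileup_fraction = 0.7,
                              max_tags = 5L) {
  need <- c("read_id", "chrom", "pos", "strand", "n_hits")
  if (!all(need %in% names(alignments)))
    stop("alignments must have columns: ", paste(need, collapse = ", "))
  unsorted <- tapply(alignments$pos, alignments$chrom, is.unsorted)
  if (any(unlist(unsorted)))
    stop("alignments must be coordinate-sorted within each chromosome")
  # (1) multi-mapping filter
  al <- alignments[alignments$n_hits <= 4L, , drop = FALSE]
  # (2) pile-up removal per chromosome
  keep <- rep(TRUE, nrow(al))
  for (ch in unique(al$chrom)) {
    ii <- which(al$chrom == ch)
    cnt <- table(al$pos[ii])
    upos <- as.integer(names(cnt))
    cntv <- as.integer(cnt)
    bad <- logical(length(upos))
    for (j in seq_along(upos)) {
      # windows containing upos[j]: total reads within any length-`window`
      # interval covering it; take the densest such interval
      lo <- upos[j] - window + 1L
      in_win <- upos >= lo & upos <= upos[j] + window - 1L
      cand <- upos[in_win]
      for (wstart in cand[cand >= lo & cand <= upos[j]]) {
        tot <- sum(cntv[upos >= wstart & upos <= wstart + window - 1L])
        if (tot > pileup_min_reads && cntv[j] >= pileup_fraction * tot) {
          bad[j] <- TRUE
          break
        }
      }
    }
    if (any(bad))
      keep[ii][al$pos[ii] %in% upos[bad]] <- FALSE
  }
  al <- al[keep, , drop = FALSE]
  # (3) tag-count trimming per (chrom, pos)
  key <- paste(al$chrom, al$pos)
  ord <- seq_len(nrow(al))
  nth <- ave(ord, key, FUN = seq_along)
  al[nth <= max_tags, , drop = FALSE]
}

#' Construct a peak table
#'
#' @param chrom,start,end,score,summit Vectors: chromosome, 0-based
#'   half-open interval, kernel-density score (>= 0), and summit position
#'   (the location of the score maximum; defaults to the interval midpoint).
#' @return `data.frame` of class `peak_table`.
#' @export
peak_table <- function(chrom, start, end, score,
                       summit = floor((start + end) / 2)) {
  if (any(start >= end)) stop("peaks must have start < end")
  if (any(score < 0)) stop("peak scores must be >= 0")
  structure(data.frame(chrom = as.character(chrom), start = as.integer(start),
                       end = as.integer(end), score = as.numeric(score),
                       summit = as.integer(summit), stringsAsFactors = FALSE),
            class = c("peak_table", "data.frame"))
}

#' Read a BED-like peak file
#'
#' Columns: chrom, start, end, name, score, and optionally a 7th column with
#' the summit position (absolute coordinate); otherwise the midpoint is
#' used.
#'
#' @param path BED path (tab-separated, no header).
#' @return A [peak_table].
#' @export
read_peaks <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 5) stop("peak BED needs at least 5 columns (score in col 5)")
  summit <- if (ncol(tab) >= 7) as.integer(tab[[7]])
            else floor((tab[[2]] + tab[[3]]) / 2)
  peak_table(tab[[1]], tab[[2]], tab[[3]], tab[[5]], summit)
}

#' Normalise peak widths
#'
#' Discards peaks with extreme scores (default: above the 99.9th score
#' percentile, a guard against mitochondrial/ribosomal/repeat pile-ups),
#' then clamps widths into the range `min_width` to `max_width`: short peaks are
#' extended and long peaks trimmed around the summit, each side resized
#' proportionally to its distance from the summit, so e.g. a 40-bp peak
#' whose summit sits 10 bp from the left end grows to 100 bp with flanks in
#' ratio 1:3.  Idempotent on already-normalised input.
#'
#' @param peaks A [peak_table]; summits must lie within their peaks.
#' @param min_width,max_width Width bounds (defaults 100 and 1000 bp).
#' @param score_cutoff Absolute score above which peaks are discarded;
#'   `NULL` (default) uses the `discard_quantile` of the scores.
#' @param discard_quantile Quantile for the default cutoff (0.999).
#' @return A [peak_table] with widths in bounds.
#' @export
normalize_peaks <- function(peaks, min_width = 100L, max_width = 1000L,
                            score_cutoff = NULL, discard_quantile = 0.999) {
  bad <- peaks$summit < peaks$start | peaks$summit >= peaks$end
  if (any(bad))
    stop(sum(bad), " peaks have a summit outside the peak interval")
  if (is.null(score_cutoff))
    score_cutoff <- unname(quantile(peaks$score, discard_quantile, type = 7))
  peaks <- peaks[peaks$score <= score_cutoff, , drop = FALSE]
  w <- peaks$end - peaks$start
  target <- pmin(pmax(w, min_width), max_width)
  resize <- which(target != w)
  for (i in resize) {
    dl <- peaks$summit[i] - peaks$start[i]
    dr <- peaks$end[i] - peaks$summit[i]
    new_left <- as.integer(round(target[i] * dl / (dl + dr)))
    peaks$start[i] <- peaks$summit[i] - new_left
    peaks$end[i] <- peaks$start[i] + target[i]
  }
  peaks
}

#' Define an ensemble region set from multiple peak panels
#'
#' Takes the `top_n` highest-scoring peaks of each factor, pools them, and
#' merges overlapping intervals; the merged intervals approximate open
#' chromatin when no accessibility assay is available.  Region ids are
#' `chrom:start-end` (0-based half-open).
#'
#' @param peak_sets Named list of [peak_table]s, one per factor.
#' @param top_n Peaks contributed per factor (default 5000).
#' @return `data.frame` with columns `id`, `chrom`, `start`, `end`; no two
#'   rows overlap.
#' @export
define_regions_ensemble <- function(peak_sets, top_n = 5000L) {
  if (!length(peak_sets)) stop("no peak sets supplied")
  pooled <- do.call(rbind, lapply(peak_sets, function(p) {
    p[order(-p$score), , drop = FALSE][seq_len(min(top_n, nrow(p))), ,
                                       drop = FALSE]
  }))
  if (!nrow(pooled)) stop("no peaks in the pooled set")
  gr <- GenomicRanges::GRanges(pooled$chrom,
                               IRanges::IRanges(pooled$start + 1L,
                                                pooled$end))
  merged <- GenomicRanges::reduce(gr)
  start0 <- GenomicRanges::start(merged) - 1L
  end0 <- GenomicRanges::end(merged)
  chrom <- as.character(GenomicRanges::seqnames(merged))
  data.frame(id = sprintf("%s:%d-%d", chrom, start0, end0),
             chrom = chrom, start = start0, end = end0,
             stringsAsFactors = FALSE)
}

#' Assign factor-specific evidence to regions by peak overlap
#'
#' Each region receives the maximum score among the factor's peaks that
#' overlap it; regions with no overlapping peak receive 0 (background).
#' Chromosome names present in the regions but absent from the peaks are
#' allowed (their regions simply get 0).
#'
#' @param regions Region table from [define_regions_ensemble()] (columns
#'   `id`, `chrom`, `start`, `end`).
#' @param peaks A [peak_table] for one factor.
#' @return Named numeric vector (region id -> score), suitable for
#'   [chipseq_evidence()].
#' @export
assign_evidence <- function(regions, peaks) {
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end))
  pg <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  hits <- GenomicRanges::findOverlaps(rg, pg)
  score <- rep(0, nrow(regions))
  if (length(hits)) {
    agg <- tapply(peaks$score[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), max)
    score[as.integer(names(agg))] <- as.numeric(agg)
  }
  stats::setNames(score, regions$id)
}

#' Extract region sequences from a genome FASTA
#'
#' @param regions Region table (columns `id`, `chrom`, `start`, `end`,
#'   0-based half-open).
#' @param genome_fasta Path to the genome FASTA, or a named character vector
#'   of chromosome sequences.
#' @return A [region_set].
#' @export
region_sequences <- function(regions, genome_fasta) {
  chroms <- if (is.character(genome_fasta) && length(genome_fasta) == 1L &&
                file.exists(genome_fasta)) {
    fa <- Biostrings::readBStringSet(genome_fasta)
    stats::setNames(as.character(fa), sub("\\s.*$", "", names(fa)))
  } else genome_fasta
  missing <- setdiff(unique(regions$chrom), names(chroms))
  if (length(missing))
    stop("chromosomes absent from genome: ", paste(missing, collapse = ", "))
  seqs <- substr(chroms[regions$chrom], regions$start + 1L, regions$end)
  region_set(stats::setNames(seqs, regions$id))
}
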