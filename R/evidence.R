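# Evidence of regulation: transform raw experimental measurements into a
# per-region log-odds score e_j.  Three transforms are supported, matching
# the three assay types: ChIP-chip P-values (via a Bayes-factor calibration
# bound), ChIP-seq kernel-density peak scores (log-odds against a background
# percentile), and expression fold-changes from over-expression assays.

#' Construct an evidence set
#'
#' @param ids Character vector of region ids.
#' @param values Numeric evidence values (finite), aligned with `ids`.
#' @param type Evidence type tag.
#' @param raw Optional raw (untransformed) values.
#' @return Object of class `evidence_set` with elements `id`, `value`,
#'   `type`, `raw`.
#' @export
evidence_set <- function(ids, values,
                         type = c("raw", "chip_pvalue", "chipseq_score",
                                  "log_fold_change"),
                         raw = NULL) {
  type <- match.arg(type)
  if (length(ids) != length(values)) stop("ids and values lengths differ")
  if (anyDuplicated(ids)) stop("duplicate ids in evidence set")
  if (any(!is.finite(values))) stop("evidence values must be finite")
  structure(list(id = as.character(ids), value = as.numeric(values),
                 type = type, raw = if (is.null(raw)) values else raw),
            class = "evidence_set")
}

#' @export
print.evidence_set <- function(x, ...) {
  cat(sprintf("Evidence set: %d regions, type '%s', range [%.3g, %.3g]\n",
              length(x$id), x$type, min(x$value), max(x$value)))
  invisible(x)
}

#' @export
length.evidence_set <- function(x) length(x$id)

#' P-value calibration: approximate Bayes factors as evidence
#'
#' Interpreting a ChIP-chip P-value directly as an odds ratio of binding
#' overstates the evidence (the "P-value fallacy").  The calibration bound
#' of Sellke, Bayarri & Berger gives an upper bound on the Bayes factor of
#' binding vs non-binding under a Beta(theta, 1) family of alternatives:
#' \deqn{B_{10}(p) \le \frac{1}{-e \, p \log p}, \quad p < 1/e,}
#' and the evidence is its natural log, \eqn{e_j = \log B_{10}(p_j)}.  At
#' p = 0.001 the denominator is 0.0188, i.e. a Bayes factor of about 50
#' rather than 1000.  For p >= 1/e the bound is clamped to 1 (zero
#' evidence).  Monotone non-increasing in p.
#'
#' @param p Numeric vector of P-values in (0, 1].
#' @param neglog With `neglog = TRUE` substitute the naive
#'   \eqn{e_j = -\log p_j} transform instead of the calibrated bound.
#' @param floor Replacement value for p = 0 (applied with a warning).
#' @return Numeric vector of evidence values (natural log scale).
#' @examples
#' pvalue_evidence(0.001) # log(1 / 0.0188) = 3.97
#' @export
pvalue_evidence <- function(p, neglog = FALSE, floor = 1e-300) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("P-values must lie in (0, 1]")
  if (any(p == 0)) {
    warning("P-value of 0 replaced by floor = ", floor)
    p[p == 0] <- floor
  }
  if (neglog) return(-log(p))
  b10 <- ifelse(p < exp(-1), 1 / (-exp(1) * p * log(p)), 1)
  log(pmax(b10, 1))
}

#' ChIP-seq peak densities as evidence
#'
#' Per-region evidence from the maximum kernel-density read score of each
#' region: a log-odds ratio \eqn{e_j = \log(s_j / b)} against a background
#' score `b`, taken as the 85th percentile (linear interpolation) of the
#' strictly positive scores.  Regions with score 0 are floored at 1e-3 times
#' the smallest positive score.
#'
#' @param kde_max Named numeric vector: maximum kernel-density score per
#'   region (>= 0, at least one strictly positive).
#' @param background_percentile Background percentile of the positive
#'   scores, default 85.
#' @return An [evidence_set] of type `chipseq_score`.
#' @export
chipseq_evidence <- function(kde_max, background_percentile = 85) {
  if (is.null(names(kde_max))) stop("kde_max must be named by region id")
  if (any(kde_max < 0)) stop("kernel density scores must be >= 0")
  pos <- kde_max[kde_max > 0]
  if (!length(pos)) stop("all kernel density scores are zero")
  b <- unname(quantile(pos, background_percentile / 100, type = 7))
  floor_score <- min(pos) * 1e-3
  e <- log(pmax(kde_max, floor_score) / b)
  evidence_set(names(kde_max), unname(e), type = "chipseq_score",
               raw = unname(kde_max))
}

#' Expression fold-change as evidence
#'
#' For factor over-expression assays (e.g. miRNA transfection), evidence is
#' the log2 fold-change oriented so that down-regulation upon induction
#' yields positive evidence: \eqn{e_j = -\log_2(x_{after}/x_{before})}.
#'
#' @param x_before,x_after Strictly positive expression values (vectors).
#' @param ids Optional region ids (names for the result).
#' @param repressor Default `TRUE`: down-regulation is positive evidence.
#'   Set `FALSE` for activator studies to flip the sign.
#' @return Numeric vector of evidence values (named if `ids` given).
#' @export
expression_evidence <- function(x_before, x_after, ids = NULL,
                                repressor = TRUE) {
  bad <- which(!(x_before > 0) | !(x_after > 0))
  if (length(bad)) {
    lab <- if (!is.null(ids)) paste(head(ids[bad], 5), collapse = ", ")
           else paste(head(bad, 5), collapse = ", ")
    stop("non-positive expression values for: ", lab)
  }
  e <- -log2(x_after / x_before)
  if (!repressor) e <- -e
  if (!is.null(ids)) names(e) <- ids
  e
}

#' Read a two-column evidence table
#'
#' Tab-separated file of (region id, raw value); the declared evidence type
#' selects the transform applied to the raw column.
#'
#' @param path TSV path (no header by default; a header line `id value` is
#'   detected and skipped).
#' @param type One of `chip_pvalue`, `chipseq_score`, `log_fold_change`,
#'   `raw`.  `chip_pvalue` applies [pvalue_evidence()]; `chipseq_score`
#'   applies [chipseq_evidence()]; `log_fold_change` and `raw` are used
#'   as-is.
#' @param regions Optional [region_set] to cross-validate ids against.
#' @param lenient With a region set: drop (with a warning) evidence rows for
#'   unknown regions instead of erroring.
#' @param ... Passed to the transform (e.g. `neglog`,
#'   `background_percentile`).
#' @return An [evidence_set].
#' @export
read_evidence <- function(path, type = c("raw", "chip_pvalue",
                                         "chipseq_score", "log_fold_change"),
                          regions = NULL, lenient = FALSE, ...) {
  type <- match.arg(type)
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("evidence table must have two columns")
  if (is.na(suppressWarnings(as.numeric(tab[1, 2])))) tab <- tab[-1, ]
  ids <- as.character(tab[[1]])
  raw <- as.numeric(tab[[2]])
  if (anyNA(raw)) stop("non-numeric evidence values in ", path)
  if (!is.null(regions)) {
    unknown <- setdiff(ids, regions$id)
    if (length(unknown)) {
      if (!lenient)
        stop(length(unknown), " evidence ids not in region set, e.g. ",
             paste(head(unknown, 5), collapse = ", "))
      warning("dropping ", length(unknown), " evidence rows for unknown regions")
      keep <- ids %in% regions$id
      ids <- ids[keep]; raw <- raw[keep]
    }
    missing <- setdiff(regions$id, ids)
    if (length(missing))
      stop(length(missing), " regions lack evidence, e.g. ",
           paste(head(missing, 5), collapse = ", "))
  }
  switch(type,
    chip_pvalue = evidence_set(ids, pvalue_evidence(raw, ...),
                               type = "chip_pvalue", raw = raw),
    chipseq_score = chipseq_evidence(stats::setNames(raw, ids), ...),
    log_fold_change = evidence_set(ids, raw, type = "log_fold_change"),
    raw = evidence_set(ids, raw, type = "raw")
  )
}
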