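# PSSM construction, similarity, co-occurrence testing and clustering.

make_result <- function(motif, positive, score = 1) {
  structure(list(motif = motif, positive = positive, score = score,
                 n = length(positive)), class = "motif_result")
}

test_that("PSSMs count aligned occurrence windows", {
  seqs <- c(a = "TTACGTATT", b = "GGACGTAGG", c = "CCACGTACC")
  regions <- region_set(seqs)
  idx <- build_index(regions)
  p <- motif_pssm(make_result("ACGTA", names(seqs)), regions, idx)
  expect_s3_class(p, "pssm")
  expect_equal(unname(p$mat[, 1]), c(1, 0, 0, 0))     # all words ACGTA
  expect_identical(pssm_consensus(p), "ACGTA")
  # degenerate position: 3 words starting A, 1 starting T
  seqs2 <- c(a = "GGACGTAGG", b = "GGACGTAGG", c = "CCACGTACC",
             d = "CCTCGTACC")
  regions2 <- region_set(seqs2)
  idx2 <- build_index(regions2)
  p2 <- motif_pssm(make_result("WCGTA", names(seqs2)), regions2, idx2)
  expect_equal(unname(p2$mat[, 1]), c(0.75, 0, 0, 0.25))
  # reverse-strand windows are flipped into motif orientation
  seqs3 <- c(a = "TTTACGTTT")   # contains RC of ACGTA
  regions3 <- region_set(seqs3)
  p3 <- motif_pssm(make_result("ACGTA", "a"), regions3, build_index(regions3))
  expect_identical(pssm_consensus(p3), "ACGTA")
  # columns always sum to 1 on random fixtures
  set.seed(41)
  seqs4 <- random_region_seqs(30, 80)
  regions4 <- region_set(seqs4)
  idx4 <- build_index(regions4)
  for (m in c("ACGT" , "WSGTA", "RYKMA")) {
    m <- check_motif(m)
    pos <- regions_containing(idx4, m)
    if (!length(pos)) next
    pm <- motif_pssm(make_result(m, pos), regions4, idx4)
    expect_equal(colSums(pm$mat), rep(1, pm$width), tolerance = 1e-9)
  }
})

test_that("the column distance is a scaled symmetric metric on PSSMs", {
  set.seed(42)
  p <- random_pssm(6)
  expect_identical(harbison_distance(p, p), 0)
  pa <- pssm(matrix(rep(c(1, 0, 0, 0), 6), nrow = 4))
  pt <- pssm(matrix(rep(c(0, 0, 0, 1), 6), nrow = 4))
  expect_equal(harbison_distance(pa, pt), 1)
  for (i in 1:100) {
    q1 <- random_pssm(7); q2 <- random_pssm(7)
    d <- harbison_distance(q1, q2)
    expect_equal(d, harbison_distance(q2, q1))
    expect_true(d >= 0 && d <= 1)
  }
  expect_error(harbison_distance(random_pssm(5), random_pssm(6)), "widths")
})

test_that("overlap similarity maximises over shifts and orientations", {
  set.seed(43)
  p <- random_pssm(8)
  expect_equal(harbison_similarity(p, p), 1)
  # equal widths: full overlap is among the candidates
  q <- random_pssm(8)
  expect_gte(harbison_similarity(p, q), 1 - harbison_distance(p, q))
  # width-5 pair: only the two full-overlap orientations are allowed
  p5 <- random_pssm(5); q5 <- random_pssm(5)
  rc5 <- pssm(q5$mat[4:1, 5:1])
  expect_equal(harbison_similarity(p5, q5),
               max(1 - harbison_distance(p5, q5),
                   1 - harbison_distance(p5, rc5)),
               tolerance = 1e-9)
  # symmetry, including the orientation search
  for (i in 1:50) {
    a <- random_pssm(sample(5:9, 1)); b <- random_pssm(sample(5:9, 1))
    expect_equal(harbison_similarity(a, b), harbison_similarity(b, a),
                 tolerance = 1e-12)
  }
  # a shifted copy of itself is recognised at similarity 1
  wide <- random_pssm(9)
  sub <- pssm(wide$mat[, 2:8])
  expect_equal(harbison_similarity(wide, sub), 1, tolerance = 1e-12)
})

test_that("co-occurrence P-values are exact hypergeometric tails", {
  expect_identical(cooccurrence_pvalue(letters[1:3], letters[2:5],
                                       character(0), 10), 1)
  expect_equal(cooccurrence_pvalue(letters[1:5], letters[1:5], letters[1:5],
                                   10), 1 / choose(10, 5), tolerance = 1e-12)
  # brute-force oracle: closed-form tail sum for d <= 12
  set.seed(44)
  for (i in 1:50) {
    d <- sample(5:12, 1)
    ids <- letters[1:d]
    n1 <- sample(1:d, 1); n2 <- sample(1:d, 1)
    pos1 <- sample(ids, n1)
    pos2 <- sample(ids, n2)
    co <- intersect(pos1, pos2)
    j <- length(co)
    oracle <- sum(choose(n2, j:min(n1, n2)) *
                  choose(d - n2, n1 - (j:min(n1, n2)))) / choose(d, n1)
    if (j == 0) oracle <- 1
    expect_equal(cooccurrence_pvalue(pos1, pos2, co, d), oracle,
                 tolerance = 1e-9)
  }
  # monotone: more co-occurrence is never less surprising
  ps <- vapply(0:4, function(co)
    cooccurrence_pvalue(letters[1:5], letters[1:5], head(letters, co), 12),
    numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(cooccurrence_pvalue(letters[1:2], letters[1:2], letters[1:3],
                                   10), "subset")
})

test_that("similarity requires both the PSSM cutoff and co-occurrence", {
  # two interleaved motifs planted side by side co-occur within tau
  set.seed(45)
  core <- "TGACTCA"
  seqs <- vapply(1:60, function(i) {
    bg <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                collapse = "")
    if (i <= 25) paste0(substr(bg, 1, 30), core, "GG", core,
                        substr(bg, 40, 80))
    else bg
  }, character(1))
  names(seqs) <- sprintf("r%02d", 1:60)
  regions <- region_set(seqs)
  idx <- build_index(regions)
  pos <- regions_containing(idx, core)
  r1 <- make_result(core, pos, score = 3)
  r2 <- make_result("TGACTCAG", regions_containing(idx, "TGACTCAG"),
                    score = 2.5)
  r1$pssm <- motif_pssm(r1, regions, idx)
  r2$pssm <- motif_pssm(r2, regions, idx)
  expect_true(motifs_similar(r1, r2, idx, 60))
  expect_true(harbison_similarity(r1$pssm, r2$pssm) >= 0.75)
  # dissimilar PSSM fails condition 1 even with perfect co-occurrence
  r3 <- make_result("GGGGG", pos, score = 1)
  r3$pssm <- consensus_pssm("GGGGG")
  expect_false(motifs_similar(r1, r3, idx, 60))
})

test_that("clustering peels the ranked list into a partition", {
  set.seed(46)
  sim <- synthesize_dataset(d = 200, region_length = 120, motif = "TGACTCA",
                            planted_fraction = 0.2, effect = 3, seed = 46)
  fit <- evimotif(sim$regions, sim$evidence, a = 10, top_m = 15)
  expect_gte(length(fit$clusters), 1)
  all_members <- unlist(lapply(fit$clusters, function(cl)
    c(cl$representative$motif,
      vapply(cl$members, `[[`, character(1), "motif"))))
  expect_setequal(all_members, fit$motifs$motif)      # partition
  expect_false(anyDuplicated(all_members) > 0)
  for (cl in fit$clusters) {
    scores <- vapply(cl$members, `[[`, numeric(1), "score")
    if (length(scores))
      expect_true(all(cl$representative$score >= scores))
    expect_equal(colSums(cl$pssm$mat), rep(1, cl$pssm$width),
                 tolerance = 1e-9)
  }
  # representative scores decrease with the cluster index
  reps <- vapply(fit$clusters, function(cl) cl$representative$score,
                 numeric(1))
  expect_true(all(diff(reps) <= 0))
})

test_that("cluster PSSMs are score-weighted aligned averages", {
  set.seed(47)
  p1 <- random_pssm(7)
  r1 <- make_result("AAAAAAA", letters[1:5], score = 2)
  r1$pssm <- p1
  # singleton: representative PSSM unchanged
  cl <- structure(list(representative = r1, members = list()),
                  class = "motif_cluster")
  expect_equal(cluster_pssm(cl)$mat, p1$mat, tolerance = 1e-12)
  # equal scores, equal widths, no shift: arithmetic mean
  p2 <- pssm((p1$mat + random_pssm(7)$mat) / 2)
  # force the aligned frame by making p2 close to p1 (same best shift 0, +)
  p2 <- pssm((3 * p1$mat + random_pssm(7)$mat) / 4)
  r2 <- make_result("AAAAAAT", letters[2:6], score = 2)
  r2$pssm <- p2
  cl2 <- structure(list(representative = r1, members = list(r2)),
                   class = "motif_cluster")
  out <- cluster_pssm(cl2)
  sim <- harbison_similarity(p1, p2, details = TRUE)
  if (attr(sim, "shift") == 0 && attr(sim, "orientation") == "+")
    expect_equal(out$mat, (p1$mat + p2$mat) / 2, tolerance = 1e-9)
  expect_equal(colSums(out$mat), rep(1, 7), tolerance = 1e-9)
})
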