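# Objective function, size constraints, move generators and the greedy
# seed-evolution search.

test_that("enrichment score is the centred, scaled positive-set average", {
  e <- c(2, 2, rep(0, 8))
  expect_equal(enrichment_score(e, 1:2), 2 * sqrt(2), tolerance = 1e-12)
  # agreement with an independent brute-force evaluation on random subsets
  set.seed(31)
  for (i in 1:50) {
    ev <- rnorm(30)
    pos <- sample(30, sample(1:29, 1))
    expect_equal(enrichment_score(ev, pos), oracle_enrichment(ev, pos),
                 tolerance = 1e-12)
  }
})

test_that("enrichment score has the documented degeneracies and invariance", {
  expect_identical(enrichment_score(rep(3, 10), 1:4), 0)   # constant evidence
  expect_identical(enrichment_score(rnorm(10), 1:10), 0)   # whole-set subset
  set.seed(32)
  ev <- rnorm(40)
  pos <- sample(40, 10)
  base <- enrichment_score(ev, pos)
  expect_equal(enrichment_score(2.7 * ev + 13, pos), base, tolerance = 1e-9)
  # finite-population correction scales the denominator
  fpc <- sqrt((40 - 10) / (40 - 1))
  expect_equal(enrichment_score(ev, pos, finite_population = TRUE),
               base / fpc, tolerance = 1e-12)
  # id-based positive sets agree with index-based ones
  es <- evidence_set(sprintf("g%02d", 1:40), ev)
  expect_equal(enrichment_score(es, sprintf("g%02d", pos)), base)
})

test_that("selection score binarises the evidence at the threshold", {
  e <- c(2, 2, rep(0, 8))
  expect_equal(selection_score(e, 1:2, k = 1),
               enrichment_score(c(1, 1, rep(0, 8)), 1:2))
  expect_identical(selection_score(e, 1:2, k = -5), 0)  # all indicators 1
  # moving k between adjacent order statistics changes nothing
  set.seed(33)
  ev <- rnorm(25)
  pos <- sample(25, 8)
  ks <- sort(ev)
  mid <- (ks[10] + ks[11]) / 2
  expect_equal(selection_score(ev, pos, k = mid),
               selection_score(ev, pos, k = ks[10] + 1e-9))
})

test_that("positive-set size bounds are inclusive with a floored upper end", {
  cfg <- search_config(preset = "chip-chip")   # a = 20, b = 0.15
  expect_false(size_constraint_ok(19, 1000, cfg))
  expect_true(size_constraint_ok(20, 1000, cfg))
  expect_true(size_constraint_ok(150, 1000, cfg))
  expect_false(size_constraint_ok(151, 1000, cfg))
  cfg2 <- search_config(preset = "chip-seq")   # a = 100, b = 0.30
  expect_true(size_constraint_ok(10500, 35000, cfg2))
  expect_false(size_constraint_ok(10501, 35000, cfg2))
  expect_false(size_constraint_ok(99, 35000, cfg2))
})

test_that("extension appends and prepends each base", {
  expect_setequal(extension_moves("ACGTA"),
                  c("AACGTA", "CACGTA", "GACGTA", "TACGTA",
                    "ACGTAA", "ACGTAC", "ACGTAG", "ACGTAT"))
  expect_length(extension_moves(strrep("A", 20)), 0)
  for (cand in extension_moves("WSNGT"))
    expect_true(grepl("WSNGT", cand, fixed = TRUE))
})

test_that("truncation drops one flank and requires length 6", {
  expect_setequal(truncation_moves("ACGTAC"), c("CGTAC", "ACGTA"))
  expect_length(truncation_moves("ACGTA"), 0)
  for (w in 6:20)
    expect_length(truncation_moves(strrep("A", w)), 2)
})

test_that("degeneracy moves follow the per-symbol update rules", {
  cand <- degeneracy_moves("AAAAA")
  expect_length(cand, 15)   # 3k for a non-degenerate k-mer
  expect_true(all(c("MAAAA", "RAAAA", "WAAAA") %in% cand))
  # fully double-degenerate: only interior positions can widen to N (k - 2)
  expect_setequal(degeneracy_moves("WWWWW"), c("WNWWW", "WWNWW", "WWWNW"))
  # terminal double-degenerate symbols generate no candidate
  expect_length(degeneracy_moves("RCGTA"), 12)
  expect_length(degeneracy_moves("NNN"), 0)
  # one position changes per candidate and N never reaches the flanks
  for (cand in degeneracy_moves("RCGTW")) {
    expect_identical(nchar(cand), 5L)
    expect_false(substr(cand, 1, 1) == "N" || substr(cand, 5, 5) == "N")
    diff <- sum(strsplit(cand, "")[[1]] != strsplit("RCGTW", "")[[1]])
    expect_identical(diff, 1L)
  }
})

test_that("the move neighbourhood is the de-duplicated union", {
  nb5 <- motif_neighborhood("ACGTA")
  expect_length(nb5, 8 + 0 + 15)
  nb6 <- motif_neighborhood("ACGTAC")
  expect_length(nb6, 8 + 2 + 18)
  expect_false("ACGTA" %in% nb5)
  expect_false(anyDuplicated(nb6) > 0)
})

test_that("seed enumeration pools reverse complements only in dna mode", {
  dna <- enumerate_seeds(search_config(mode = "dna"))
  expect_length(dna, 512)
  expect_false(anyDuplicated(dna) > 0)
  expect_true(all(vapply(dna, motif_canonical, character(1)) == dna))
  rna <- enumerate_seeds(search_config(mode = "rna"))
  expect_length(rna, 1024)
  expect_true(all(nchar(dna) == 5))
  expect_false(any(grepl("[^ACGT]", rna)))
})

test_that("some seed evolves onto the planted positive set", {
  sim <- synthesize_dataset(d = 500, region_length = 200, motif = "TGACTCA",
                            planted_fraction = 0.1, effect = 3, noise_sd = 1,
                            seed = 101)
  fit <- evimotif(sim$regions, sim$evidence, top_m = 20, cluster = FALSE)
  jaccards <- vapply(fit$results, function(r) {
    length(intersect(r$positive, sim$truth$planted_ids)) /
      length(union(r$positive, sim$truth$planted_ids))
  }, numeric(1))
  expect_gte(max(jaccards), 0.8)
  expect_true(all(vapply(fit$results, function(r)
    size_constraint_ok(r$n, 500, fit$config), logical(1))))
})

test_that("evolution strictly improves the score of a valid seed", {
  # short regions keep 5-mer positive sets inside the admissible window
  sim <- synthesize_dataset(d = 200, region_length = 60, motif = "TGACTCA",
                            planted_fraction = 0.12, effect = 3,
                            noise_sd = 1, seed = 102)
  idx <- build_index(sim$regions)
  cfg <- search_config(a = 10, b = 0.25)
  seed <- motif_canonical("GACTC")
  seed_score <- enrichment_score(sim$evidence,
                                 regions_containing(idx, seed))
  expect_true(size_constraint_ok(length(regions_containing(idx, seed)),
                                 200, cfg))
  res <- greedy_evolve(seed, idx, sim$evidence, cfg)
  expect_gte(res$score, seed_score)
  expect_gte(res$steps, 0L)
})

test_that("seeds whose positive set violates the size bounds are invalid", {
  seqs <- stats::setNames(replicate(200, paste0("AAAAA", paste(
    sample(c("C", "G"), 30, replace = TRUE), collapse = ""))),
    sprintf("r%03d", 1:200))
  idx <- build_index(region_set(seqs))
  ev <- evidence_set(names(seqs), rnorm(200))
  expect_null(greedy_evolve("AAAAA", idx, ev))     # present in every region
  expect_null(greedy_evolve("ACGAC", idx, ev))     # present in none
})

test_that("evolved motifs always satisfy the size constraint", {
  set.seed(34)
  seqs <- random_region_seqs(150, 120)
  idx <- build_index(region_set(seqs))
  ev <- evidence_set(names(seqs), rnorm(150))
  cfg <- search_config(a = 10, b = 0.15)
  for (seed in sample(enumerate_seeds(cfg), 25)) {
    res <- greedy_evolve(seed, idx, ev, cfg)
    if (is.null(res)) next
    expect_true(size_constraint_ok(res$n, 150, cfg))
    expect_gte(res$score, -Inf)
  }
})

test_that("conservation refinement filters by ortholog co-occurrence", {
  seqs <- c(r1 = "AATGACTCATT", r2 = "CCTGACTCAGG", r3 = "GGTGACTCACC")
  orth <- list(
    spec1 = c(r1 = "TTTGACTCATT", r2 = "GGGGGGGGGGG"),  # r2 lost the site
    spec2 = c(r1 = "AATGACTCAAA")                        # r3 has no ortholog
  )
  regions <- region_set(seqs, orthologs = orth)
  pos <- c("r1", "r2", "r3")
  refined <- conservation_refine(pos, "TGACTCA", regions)
  expect_identical(refined, c("r1", "r3"))
  expect_true(all(refined %in% pos))
  # with orthologs identical to the primaries, refinement is a no-op
  regions2 <- region_set(seqs, orthologs = list(same = seqs))
  expect_identical(conservation_refine(pos, "TGACTCA", regions2), pos)
  # and a conservation-enabled search equals the conservation-off search
  sim <- synthesize_dataset(d = 120, region_length = 100, motif = "TGACTCA",
                            planted_fraction = 0.25, effect = 3, seed = 35)
  rset <- region_set(stats::setNames(sim$regions$seq, sim$regions$id),
                     orthologs = list(mirror = stats::setNames(
                       sim$regions$seq, sim$regions$id)))
  fit_off <- evimotif(sim$regions, sim$evidence, a = 10, top_m = 5,
                      cluster = FALSE)
  fit_on <- evimotif(rset, sim$evidence, a = 10, top_m = 5,
                     conservation = TRUE, cluster = FALSE)
  expect_identical(fit_off$motifs, fit_on$motifs)
})

test_that("the ranked search is sorted, deterministic and scale-invariant", {
  sim <- synthesize_dataset(d = 150, region_length = 120, motif = "TGACTCA",
                            planted_fraction = 0.2, effect = 3, seed = 36)
  fit1 <- evimotif(sim$regions, sim$evidence, a = 10, top_m = 20,
                   cluster = FALSE)
  expect_true(all(diff(fit1$motifs$score) <= 0))
  expect_false(anyDuplicated(fit1$motifs$motif) > 0)
  fit2 <- evimotif(sim$regions, sim$evidence, a = 10, top_m = 20,
                   cluster = FALSE)
  expect_identical(fit1$motifs, fit2$motifs)
  ev3 <- evidence_set(sim$evidence$id, 5 * sim$evidence$value + 2)
  fit3 <- evimotif(sim$regions, ev3, a = 10, top_m = 20, cluster = FALSE)
  expect_identical(fit1$motifs$motif, fit3$motifs$motif)
  expect_equal(fit1$motifs$score, fit3$motifs$score, tolerance = 1e-9)
})

test_that("miRNA seed motifs are the reverse complements of positions 2-7/1-7/2-8/1-8", {
  seeds <- mirna_seed_motifs("UGGAAUGUAAAGAAGUAUGUAU")  # miR-1
  expect_identical(unname(seeds), c("CATTCC", "CATTCCA", "ACATTCC",
                                    "ACATTCCA"))
  expect_identical(unname(nchar(seeds)), c(6L, 7L, 7L, 8L))
  expect_error(mirna_seed_motifs("UGGAAUG"), "at least 8")
})

test_that("the evolved search scores at least the canonical miRNA seeds", {
  # plant a seed-match site in 3' UTRs with down-regulation evidence
  mirna <- "UGGAAUGUAAAGAAGUAUGUAU"
  sim <- synthesize_dataset(d = 200, region_length = 150, motif = "ACATTCC",
                            planted_fraction = 0.12, effect = 2.5,
                            noise_sd = 1, seed = 37)
  idx <- build_index(sim$regions)
  cfg <- search_config(mode = "rna", a = 10, b = 0.2)
  seed_tab <- mirna_seed_scores(mirna, idx, sim$evidence, cfg)
  expect_identical(nrow(seed_tab), 4L)
  best_seed <- attr(seed_tab, "best")
  expect_true(is.finite(best_seed))
  fit <- evimotif(sim$regions, sim$evidence, mode = "rna", a = 10, b = 0.2,
                  top_m = 1, cluster = FALSE)
  expect_gte(fit$motifs$score[1], best_seed)
})
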