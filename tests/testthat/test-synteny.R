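hits <- function(q, s, ident, score = ident * 10)
  data.frame(qseqid = q, sseqid = s, pident = ident, bitscore = score)

test_that("hit tables parse with and without header", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("qseqid\tsseqid\tpident\tbitscore", "a\tb\t95.5\t800"), path)
  h <- read_hit_table(path)
  expect_equal(h$pident, 95.5)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb\t95.5\t800", path2)
  expect_equal(read_hit_table(path2), h)
})

test_that("reciprocal best hits require mutual best and the identity floor", {
  ab <- hits("a", "b", 95)
  ba <- hits("b", "a", 95)
  expect_equal(reciprocal_best_hits(ab, ba)$gene_a, "a")

  # reciprocity failure: b prefers a2
  ba2 <- rbind(hits("b", "a", 90), hits("b", "a2", 98))
  expect_equal(nrow(reciprocal_best_hits(ab, ba2)), 0L)

  # below the 80% identity floor
  expect_equal(nrow(reciprocal_best_hits(hits("a", "b", 79),
                                         hits("b", "a", 79))), 0L)
  expect_equal(nrow(reciprocal_best_hits(hits("a", "b", 80),
                                         hits("b", "a", 80))), 1L)
})

test_that("RBH output is symmetric and monotone in the identity threshold", {
  set.seed(41)
  qa <- paste0("a", sample(1:20, 60, replace = TRUE))
  sb <- paste0("b", sample(1:20, 60, replace = TRUE))
  ident <- runif(60, 70, 100)
  ab <- hits(qa, sb, ident)
  ba <- hits(sb, qa, ident)
  fwd <- reciprocal_best_hits(ab, ba, 75)
  rev <- reciprocal_best_hits(ba, ab, 75)
  expect_equal(fwd$gene_a, sort(rev$gene_b))
  counts <- vapply(c(70, 75, 80, 85, 90, 95), function(th)
    nrow(reciprocal_best_hits(ab, ba, th)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("synteny follows plurality homoeology", {
  mk <- function(genes, chr, prefix, lengths) {
    genetic_map(data.frame(
      locus_id = paste0(prefix, seq_along(genes)), gene_id = genes,
      chromosome = chr, position_cM = seq_along(genes) * 5,
      family_id = NA_character_, species = "focal"), lengths)
  }
  ga <- paste0("a", 1:10); gb <- paste0("b", 1:10)
  la <- c(`1` = 100); lb <- c(`3` = 100, `5` = 100)
  map_a <- mk(ga, "1", "la", la)
  map_b <- mk(gb, c(rep("3", 9), "5"), "lb", lb)
  pairs <- data.frame(gene_a = ga, gene_b = gb)
  syn <- synteny_links(map_a, map_b, pairs)
  expect_equal(syn$homoeology$chr_b, "3")
  expect_equal(syn$pct_syntenic, 90)

  map_b2 <- mk(gb, "3", "lb", c(`3` = 100))
  expect_equal(synteny_links(map_a, map_b2, pairs)$pct_syntenic, 100)

  empty <- synteny_links(map_a, map_b, pairs[0, ])
  expect_true(is.na(empty$pct_syntenic))
})

test_that("collinearity equals the longest nondecreasing subsequence", {
  lk <- function(b) data.frame(pos_a = seq_along(b), pos_b = b)
  r <- collinearity(lk(c(1, 2, 5, 3, 4)), orientation_aware = FALSE)
  expect_equal(r$pct_collinear, 80)
  expect_equal(collinearity(lk(1:8))$pct_collinear, 100)
  rev_ <- collinearity(lk(8:1))
  expect_equal(rev_$pct_collinear, 100)
  expect_equal(rev_$orientation, "reverse")
  expect_equal(collinearity(lk(8:1), orientation_aware = FALSE)$pct_collinear,
               100 / 8)
})

test_that("LIS matches exhaustive search for small link sets", {
  set.seed(43)
  for (rep in 1:15) {
    n <- sample(3:12, 1)
    b <- sample(n, n)                     # a random permutation
    if (rep %% 3 == 0) b[sample(n, 2)] <- b[sample(n, 2)]  # inject ties
    r <- collinearity(data.frame(pos_a = seq_len(n), pos_b = b),
                      orientation_aware = FALSE)
    expect_equal(sum(r$collinear), brute_lis_length(b))
  }
})

test_that("conserved segments respect the gap cap and measure coverage", {
  map1 <- toy_map(seq(5, 95, by = 5))
  lk <- data.frame(chr_a = "1", chr_b = "1",
                   pos_a = c(10, 20, 30, 40, 50),
                   pos_b = c(11, 21, 31, 41, 51))
  cs <- conserved_segments(lk, map1, map1, max_gap = 20)
  expect_equal(nrow(cs$segments), 1L)
  expect_equal(cs$coverage_a, 40)

  lk2 <- data.frame(chr_a = "1", chr_b = "1", pos_a = c(10, 60),
                    pos_b = c(10, 60))
  cs2 <- conserved_segments(lk2, map1, map1, max_gap = 20)
  expect_equal(nrow(cs2$segments), 2L)
  expect_equal(cs2$coverage_a, 0)
})

test_that("an identical map pair is fully syntenic and collinear", {
  sp <- simulate_map_pair(scenario_config(seed = 17, jitter_sd = 0,
                                          rearrangements = 0))
  sa <- synteny_analysis(sp$map_a, sp$map_b, sp$ab, sp$ba)
  expect_equal(sa$pct_syntenic, 100)
  expect_equal(sa$pct_collinear, 100)
  # decoys capped below the identity floor never enter the RBH set
  expect_equal(nrow(sa$rbh), nrow(sp$truth$orthologs))
  expect_equal(sa$rbh$gene_b,
               sp$truth$orthologs$gene_b[match(sa$rbh$gene_a,
                                               sp$truth$orthologs$gene_a)])
})

test_that("single-gene translocations lower synteny proportionally", {
  pct <- vapply(1:30, function(s) {
    sp <- simulate_map_pair(scenario_config(seed = 100 + s,
                                            rearrangements = 5,
                                            jitter_sd = 0))
    synteny_analysis(sp$map_a, sp$map_b, sp$ab, sp$ba)$pct_syntenic
  }, numeric(1))
  expected <- 100 * 145 / 150
  se <- 100 * sqrt((145 / 150) * (5 / 150) / 150) / sqrt(30)
  expect_lt(abs(mean(pct) - expected), 3 * se + 0.5)
})

test_that("synteny decays on average as rearrangements accumulate", {
  mean_pct <- vapply(c(0, 2, 5), function(t) {
    mean(vapply(1:12, function(s) {
      sp <- simulate_map_pair(scenario_config(seed = 200 + s,
                                              rearrangements = t,
                                              jitter_sd = 0))
      synteny_analysis(sp$map_a, sp$map_b, sp$ab, sp$ba)$pct_syntenic
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_pct) < 0))
})
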