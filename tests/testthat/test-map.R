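test_that("map TSV round-trips through write and read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tgene_id\tchromosome\tposition_cM\tfamily_id\tspecies",
               "L1\tG1\t1\t10.5\tNA\tfocal",
               "L2\tG2\t1\t20.0\tFa\tfocal",
               "L3\tG3\t1\t99.9\tFa\tfocal"), path)
  m <- read_map_tsv(path, lengths = c(`1` = 100))
  expect_s3_class(m, "genetic_map")
  expect_equal(nrow(m$loci), 3L)

  m2 <- random_map(50, seed = 1)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_map_tsv(m2, out)
  m3 <- read_map_tsv(out, lengths = m2$lengths)
  expect_equal(m3$loci, m2$loci)
  expect_equal(m3$lengths, m2$lengths)
})

test_that("map validation rejects bad input", {
  df <- data.frame(locus_id = "L1", gene_id = "G1", chromosome = "1",
                   position_cM = 120)
  expect_error(genetic_map(df, c(`1` = 100)), "outside")
  df2 <- data.frame(locus_id = c("L1", "L1"), gene_id = c("G1", "G2"),
                    chromosome = "1", position_cM = c(1, 2))
  expect_error(genetic_map(df2, c(`1` = 100)), "duplicate")
  expect_error(genetic_map(data.frame(locus_id = "L1", gene_id = "G1",
                                      chromosome = "7", position_cM = 1),
                           c(`1` = 100)), "undeclared")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tgene_id\tchromosome\tposition_cM",
               "L1\tG1\t1\tnot_a_number"), path)
  expect_error(read_map_tsv(path, c(`1` = 100)), "line")
})

test_that("donor loci transfer to flanking-anchor midpoints", {
  ref <- genetic_map(
    data.frame(locus_id = c("r1", "r2"), gene_id = c("gA", "gB"),
               chromosome = "1", position_cM = c(10, 20)), c(`1` = 100))
  don <- genetic_map(
    data.frame(locus_id = c("d1", "d2", "d3", "d4"),
               gene_id = c("gA", "gX", "gB", "gY"),
               chromosome = "c7", position_cM = c(5, 7, 9, 30)),
    c(c7 = 50))
  expect_warning(tr <- transfer_donor_loci(ref, don, c("gA", "gB")),
                 "outside the anchor span")
  gx <- tr$loci[tr$loci$gene_id == "gX", ]
  expect_equal(gx$position_cM, 15)   # midpoint of 10 and 20
  expect_equal(gx$chromosome, "1")
  expect_equal(gx$species, "donor")
  expect_equal(attr(tr, "n_transferred"), 1L)
  # reference loci untouched
  expect_equal(tr$loci[tr$loci$species == "focal", names(ref$loci)],
               ref$loci, ignore_attr = TRUE)
})

test_that("donor locus on an anchor lands on the anchor position", {
  ref <- genetic_map(
    data.frame(locus_id = c("r1", "r2"), gene_id = c("gA", "gB"),
               chromosome = "1", position_cM = c(10, 20)), c(`1` = 100))
  don <- genetic_map(
    data.frame(locus_id = c("d1", "d2", "d3"),
               gene_id = c("gA", "gZ", "gB"),
               chromosome = "c7", position_cM = c(5, 5, 9)), c(c7 = 50))
  tr <- transfer_donor_loci(ref, don, c("gA", "gB"))
  expect_equal(tr$loci$position_cM[tr$loci$gene_id == "gZ"], 10)
})

test_that("anchor order conflicts raise an error", {
  ref <- genetic_map(
    data.frame(locus_id = c("r1", "r2"), gene_id = c("gA", "gB"),
               chromosome = "1", position_cM = c(20, 10)), c(`1` = 100))
  don <- genetic_map(
    data.frame(locus_id = c("d1", "d2", "d3"),
               gene_id = c("gA", "gX", "gB"),
               chromosome = "c7", position_cM = c(5, 7, 9)), c(c7 = 50))
  expect_error(transfer_donor_loci(ref, don, c("gA", "gB")),
               "order conflict")
})

test_that("all interior donor loci transfer in a generated scenario", {
  set.seed(7)
  anchor_ref <- seq(5, 195, by = 10)      # 20 anchors on the reference
  ref <- genetic_map(
    data.frame(locus_id = paste0("ra", seq_along(anchor_ref)),
               gene_id = paste0("anc", seq_along(anchor_ref)),
               chromosome = "1", position_cM = anchor_ref), c(`1` = 200))
  donor_only <- runif(58, min(anchor_ref) + 0.1, max(anchor_ref) - 0.1)
  don <- genetic_map(
    data.frame(locus_id = c(paste0("da", seq_along(anchor_ref)),
                            paste0("dx", seq_len(58))),
               gene_id = c(paste0("anc", seq_along(anchor_ref)),
                           paste0("new", seq_len(58))),
               chromosome = "d1",
               position_cM = c(anchor_ref / 2, donor_only / 2)),
    c(d1 = 100))
  tr <- transfer_donor_loci(ref, don, paste0("anc", seq_along(anchor_ref)))
  expect_equal(attr(tr, "n_transferred"), 58L)
  # every transferred position lies inside its flanking-anchor interval
  moved <- tr$loci[tr$loci$species == "donor", ]
  expect_true(all(moved$position_cM >= min(anchor_ref) &
                    moved$position_cM <= max(anchor_ref)))
})

test_that("co-localization groups capture exact position ties", {
  m <- toy_map(c(12.3, 12.3, 40.0))
  g <- colocalized_groups(m)
  expect_length(g, 1L)
  expect_length(g[[1]]$locus_ids, 2L)

  m2 <- toy_map(c(1, 2, 3, 4))
  expect_length(colocalized_groups(m2), 0L)
})

test_that("planted co-localization groups are recovered exactly", {
  set.seed(21)
  # 32 groups totalling 71 genes at identical positions, plus scatter
  sizes <- c(rep(2, 25), rep(3, 7))          # 50 + 21 = 71 genes
  stopifnot(sum(sizes) == 71, length(sizes) == 32)
  pos_groups <- seq(2, 95, length.out = 32)
  positions <- c(rep(pos_groups, sizes),
                 pos_groups + 0.73)           # 32 distinct singletons
  m <- toy_map(positions)
  g <- colocalized_groups(m, epsilon = 0)
  expect_length(g, 32L)
  # groups partition the tied loci and are disjoint
  ids <- unlist(lapply(g, `[[`, "locus_ids"))
  expect_equal(anyDuplicated(ids), 0L)
  expect_equal(sum(lengths(lapply(g, `[[`, "locus_ids"))), 71L)
})

test_that("co-expression flags follow the one-sided positive rule", {
  v <- c(1, 3, 2, 5, 4, 6, 7, 8)
  expr <- rbind(a = v, b = v, c = -v, d = rep(2, 8))
  colnames(expr) <- paste0("t", 1:8)
  res <- coexpression_flag(c("a", "b"), expr, alpha = 0.01)
  expect_equal(res$r, 1)
  expect_true(res$coregulated)
  expect_true(attr(res, "group_coregulated"))

  res2 <- coexpression_flag(c("a", "c"), expr, alpha = 0.01)
  expect_equal(res2$r, -1)
  expect_false(res2$coregulated)   # negative correlation is not co-regulation

  res3 <- coexpression_flag(c("a", "d"), expr)
  expect_false(res3$testable)

  set.seed(3)
  expr4 <- rbind(x = rnorm(8), y = rnorm(8))
  colnames(expr4) <- paste0("t", 1:8)
  res4 <- coexpression_flag(c("x", "y"), expr4, alpha = 0.05,
                            alternative = "two.sided")
  expect_gt(res4$p, 0.05)
})

test_that("term enrichment matches the exact hypergeometric tail", {
  genes <- c(paste0("f", 1:10), paste0("b", 1:10))
  terms <- rbind(data.frame(gene_id = paste0("f", 1:10), term = "T1"),
                 data.frame(gene_id = paste0("b", 1:10), term = "T2"))
  e <- term_enrichment(paste0("f", 1:10), genes, terms)
  # fully separated 2x2 table (10,0;0,10): p = 2 / choose(20,10)
  expect_equal(e$p[e$term == "T1"], 2 / choose(20, 10), tolerance = 1e-10)

  # equal proportions: odds ratio 1, p = 1
  terms2 <- data.frame(gene_id = genes, term = "T3")
  e2 <- term_enrichment(paste0("f", 1:10), genes, terms2)
  expect_equal(e2$p, 1)

  # unused terms never appear
  terms3 <- rbind(terms2, data.frame(gene_id = "absent", term = "T4"))
  e3 <- term_enrichment(paste0("f", 1:10), genes, terms3)
  expect_false("T4" %in% e3$term)

  expect_error(term_enrichment(character(0), genes, terms), "empty")
  expect_error(term_enrichment("zz", genes, terms), "subset")
})

test_that("Fisher p is invariant under table transposition", {
  # tested through the public surface by swapping foreground role
  genes <- c(paste0("f", 1:8), paste0("b", 1:12))
  terms <- data.frame(gene_id = c(paste0("f", 1:5), paste0("b", 1:3)),
                      term = "T")
  p1 <- term_enrichment(paste0("f", 1:8), genes, terms)$p
  p2 <- stats::fisher.test(matrix(c(5, 3, 3, 9), 2))$p.value
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(p2, stats::fisher.test(t(matrix(c(5, 3, 3, 9), 2)))$p.value,
               tolerance = 1e-12)
})
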