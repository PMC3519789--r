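test_that("Newick trees parse with supports and taxon classes", {
  st <- tree_of("((Pg1,Pg2)95,(AT1,Os1));")
  expect_s3_class(st, "support_tree")
  expect_length(st$labels, 4L)
  expect_length(st$splits, 1L)
  expect_equal(st$supports, 95)
  expect_setequal(unique(st$classes), c("focal_gymno", "angiosperm"))

  expect_error(tree_of("((Zz9,Pg2),(AT1,Os1));"), "prefix")
})

test_that("tree sets round-trip through Newick files", {
  set.seed(8)
  trees <- lapply(1:500, function(i) {
    tr <- ape::rtree(6)
    tr$tip.label <- paste0("Pg", 1:6)
    tr$node.label <- NULL
    as_support_tree(tr)
  })
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree_set(trees, path)
  back <- read_tree_set(path)
  expect_length(back, 500L)
  # split sets survive the round trip
  for (i in c(1, 250, 500))
    expect_setequal(split_keys(back[[i]]), split_keys(trees[[i]]))
})

test_that("majority-rule consensus keeps exactly the >50% splits", {
  t1 <- tree_of("((Pg1,Pg2),(Pg3,Pg4));")   # split {Pg1,Pg2}
  t3 <- tree_of("((Pg1,Pg3),(Pg2,Pg4));")
  cons <- majority_rule_consensus(list(t1, t1, t3))
  expect_length(cons$splits, 1L)
  expect_equal(cons$supports, 200 / 3, tolerance = 1e-10)
  expect_setequal(split_keys(cons), split_keys(t1))

  same <- majority_rule_consensus(list(t1, t1, t1))
  expect_setequal(split_keys(same), split_keys(t1))
  expect_true(all(same$supports == 100))

  # exactly 50% is excluded: star
  star <- majority_rule_consensus(list(t1, t3))
  expect_length(star$splits, 0L)

  expect_error(majority_rule_consensus(list(t1, tree_of("((Pg1,Pg2),(Pg3,Pg9));"))),
               "mismatched")
})

test_that("strict consensus intersects split sets", {
  t1 <- tree_of("((Pg1,Pg2),(Pg3,Pg4));")
  expect_setequal(split_keys(strict_consensus(t1, t1)), split_keys(t1))

  star <- support_tree(paste0("Pg", 1:4))
  expect_length(strict_consensus(t1, star)$splits, 0L)

  a <- tree_of("((Pg1,Pg2),Pg3,(Pg4,Pg5));")
  b <- tree_of("((Pg1,Pg2),(Pg3,Pg4),Pg5);")
  sc <- strict_consensus(a, b)
  expect_length(sc$splits, 1L)
  # the surviving split separates {Pg1,Pg2} from the rest
  labs <- sc$labels[sc$splits[[1]]]
  expect_true(setequal(labs, c("Pg1", "Pg2")) ||
                setequal(labs, c("Pg3", "Pg4", "Pg5")))
})

test_that("consensus agrees with independent bipartition enumeration", {
  set.seed(14)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    trees <- lapply(1:5, function(i) {
      tr <- ape::rtree(n)
      tr$tip.label <- paste0("Pg", seq_len(n))
      tr$node.label <- NULL
      tr
    })
    # brute-force majority count over phangorn-enumerated splits
    keys <- unlist(lapply(trees, oracle_split_keys))
    tab <- table(keys)
    expected <- sort(names(tab)[tab / length(trees) > 0.5])
    cons <- majority_rule_consensus(lapply(trees, as_support_tree))
    expect_equal(sort(split_keys(cons)), expected)
    # strict consensus of the first two trees
    expected2 <- sort(intersect(oracle_split_keys(trees[[1]]),
                                oracle_split_keys(trees[[2]])))
    sc <- strict_consensus(as_support_tree(trees[[1]]),
                           as_support_tree(trees[[2]]))
    expect_equal(sort(split_keys(sc)), expected2)
  }
})

test_that("consensus splits always come from the inputs", {
  set.seed(15)
  trees <- lapply(1:7, function(i) {
    tr <- ape::rtree(7); tr$tip.label <- paste0("Pg", 1:7)
    tr$node.label <- NULL; as_support_tree(tr)
  })
  cons <- majority_rule_consensus(trees)
  all_keys <- unique(unlist(lapply(trees, split_keys)))
  expect_true(all(split_keys(cons) %in% all_keys))
  expect_true(all(cons$supports > 50 & cons$supports <= 100))
  sc <- strict_consensus(trees[[1]], trees[[2]])
  expect_true(all(split_keys(sc) %in% split_keys(trees[[1]])))
  expect_true(all(split_keys(sc) %in% split_keys(trees[[2]])))
})

test_that("pair ages follow the intervening-angiosperm rule", {
  expect_equal(classify_pair_age(tree_of("((Pg1,Pg2),(AT1,Os1));"),
                                 "Pg1", "Pg2"), "recent")
  expect_equal(classify_pair_age(tree_of("((Pg1,AT1),(Pg2,Os1));"),
                                 "Pg1", "Pg2"), "ancient")
  expect_equal(classify_pair_age(support_tree(c("Pg1", "Pg2", "AT1", "Os1")),
                                 "Pg1", "Pg2"), "undetermined")
  expect_error(classify_pair_age(tree_of("((Pg1,Pg2),(Pg3,Pt1));"),
                                 "Pg1", "Pg2"), "anchored")
})

test_that("the published methyltransferase family topology classifies as described", {
  # strict consensus with two post-GA cherries and one pre-GA duplication
  fig <- tree_of(paste0("(((Pg6-29,Pg2-68)100,(AT1,Os1)100)100,",
                        "((Pg10-23,Pg10-26)100,(AT2,Os2)100)100);"))
  expect_equal(classify_pair_age(fig, "Pg6-29", "Pg2-68"), "recent")
  expect_equal(classify_pair_age(fig, "Pg10-23", "Pg10-26"), "recent")
  for (a in c("Pg6-29", "Pg2-68"))
    for (b in c("Pg10-23", "Pg10-26"))
      expect_equal(classify_pair_age(fig, a, b), "ancient")
})

test_that("weakly supported splits collapse before classification", {
  t <- tree_of("((Pg1,Pg2)40,(AT1,Os1)40);")
  expect_equal(classify_pair_age(t, "Pg1", "Pg2", min_support = 50),
               "undetermined")
  expect_equal(classify_pair_age(t, "Pg1", "Pg2", min_support = 30),
               "recent")
})

test_that("recent and ancient calls are invariant to the rooting angiosperm", {
  cfg <- scenario_config(seed = 19, n_families = 25)
  st <- simulate_family_trees(cfg)
  for (fam in names(st$nj)[1:10]) {
    tr <- st$nj[[fam]]
    ang <- tr$labels[tr$classes == "angiosperm"]
    focal <- tr$labels[tr$classes == "focal_gymno"]
    prs <- utils::combn(focal, 2)
    for (j in seq_len(min(ncol(prs), 4))) {
      labels <- vapply(ang, function(r)
        classify_pair_age(tr, prs[1, j], prs[2, j], root_on = r),
        character(1))
      if (!any(labels == "undetermined"))
        expect_length(unique(labels), 1L)
    }
  }
})

test_that("family-level classification books pairs and tallies consistently", {
  cfg <- scenario_config(seed = 23, n_families = 30)
  st <- simulate_family_trees(cfg)
  res <- classify_families(st$nj, st$mp, st$map)
  t <- res$tally
  expect_equal(t[["congruent"]] + t[["incongruent"]], t[["total"]])
  expect_equal(t[["ancient"]] + t[["recent"]] + t[["undetermined"]],
               t[["congruent"]])
  # identical NJ/MP trees: nothing incongruent
  expect_equal(unname(t[["incongruent"]]), 0)
  # every family with k mapped members contributes choose(k, 2) pairs
  k <- table(st$map$loci$family_id)
  expect_equal(unname(t[["total"]]), sum(choose(k, 2)))
  # strict consensus emitted per family
  expect_setequal(names(res$consensus), names(st$nj))
})

test_that("disagreeing trees mark pairs incongruent", {
  nj <- list(F1 = tree_of("(((Pg1,Pg2)100,(AT1,Os1)100)100,((Pg3,Pg4)100,(AT2,Os2)100)100);"))
  mp <- list(F1 = tree_of("(((Pg1,AT1)100,(Pg2,Os1)100)100,((Pg3,Pg4)100,(AT2,Os2)100)100);"))
  map <- genetic_map(
    data.frame(locus_id = paste0("L", 1:4), gene_id = paste0("Pg", 1:4),
               chromosome = "1", position_cM = c(1, 2, 3, 4),
               family_id = "F1", species = "focal"), c(`1` = 100))
  res <- classify_families(nj, mp, map)
  lab12 <- res$pairs$label[res$pairs$gene_a == "Pg1" &
                             res$pairs$gene_b == "Pg2"]
  expect_equal(lab12, "incongruent")
  lab34 <- res$pairs$label[res$pairs$gene_a == "Pg3" &
                             res$pairs$gene_b == "Pg4"]
  expect_equal(lab34, "recent")
})

test_that("age percentage arithmetic matches tally ratios", {
  p <- age_percentages(688, 87, 102)
  expect_equal(round(unname(p["pct_ancient"]), 1), 78.4)
  expect_equal(round(unname(p["pct_recent"]), 1), 9.9)
  expect_equal(round(unname(p["pct_undetermined"]), 1), 11.6)
  expect_equal(unname(p["ratio_ancient_recent"]), 688 / 87)
})
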