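# Seeded generators for every input the pipeline consumes: genetic maps
# with planted gene-rich regions and tandem families, gene-family tree
# pairs with a known duplication history relative to the GA split,
# two-map homology scenarios with hit tables, and expression matrices.
# Ground truth is returned alongside so downstream stages can be scored
# without re-deriving it.

#' Scenario configuration for the synthetic-data generators
#'
#' Defaults describe the study conditions the generators emulate: 12
#' chromosomes with the published composite spruce map lengths, about 150
#' mapped genes per chromosome, 157 gene families (17 of them tandem,
#' single-chromosome), a ratio of roughly eight ancient duplications per
#' recent one, translocation probabilities of 0.919 (ancient) and 0.425
#' (recent), and same-chromosome duplicate distances with means 47.0 cM
#' (ancient) and 4.3 cM (recent).
#'
#' @param seed RNG seed.
#' @param lengths named chromosome lengths (cM).
#' @param genes_per_chromosome background gene count per chromosome
#'   (scalar or per-chromosome vector).
#' @param grr data.frame (chromosome, center, width, enrichment) of
#'   planted gene-rich regions, or NULL.
#' @param n_families,n_tandem_families dispersed-family and planted
#'   tandem-family counts (tandem families live on one chromosome within
#'   small windows).
#' @param family_size_p geometric parameter for family sizes
#'   (size = 2 + rgeom(p)).
#' @param fraction_ancient fraction of duplication events predating the
#'   GA split.
#' @param p_transloc named translocation probabilities per age class.
#' @param dist_mean named same-chromosome distance means (cM) per class.
#' @param nni_prob,collapse_prob tree-noise parameters: expected fraction
#'   of internal edges rearranged (NNI) / collapsed per emitted tree.
#' @param rearrangements,inversions map-pair rearrangement counts
#'   (single-gene translocations / segment inversions).
#' @param n_shared_genes genes shared by the two maps of a map pair.
#' @param jitter_sd positional jitter (cM) between the two maps.
#' @param hit_identity_mean,hit_identity_sd true-ortholog percent
#'   identity distribution (normal, truncated to [70, 100]).
#' @param decoy_prob,decoy_identity_max decoy-hit rate and identity cap.
#' @param n_tissues tissues in simulated expression matrices.
#' @return a list of class \code{scenario_config}.
#' @export
scenario_config <- function(seed = 1,
                            lengths = c(`1` = 180.6, `2` = 185.3,
                                        `3` = 172.6, `4` = 168.3,
                                        `5` = 167.1, `6` = 180.3,
                                        `7` = 204.5, `8` = 157.4,
                                        `9` = 145.8, `10` = 120.4,
                                        `11` = 171.2, `12` = 131.7),
                            genes_per_chromosome = 150,
                            grr = NULL,
                            n_families = 157,
                            n_tandem_families = 17,
                            family_size_p = 0.42,
                            fraction_ancient = 8 / 9,
                            p_transloc = c(ancient = 0.919, recent = 0.425),
                            dist_mean = c(ancient = 47.0, recent = 4.3),
                            nni_prob = 0, collapse_prob = 0,
                            rearrangements = 0, inversions = 0,
                            n_shared_genes = 150,
                            jitter_sd = 0.5,
                            hit_identity_mean = 92, hit_identity_sd = 3,
                            decoy_prob = 0.3, decoy_identity_max = 75,
                            n_tissues = 8) {
  cfg <- list(seed = seed, lengths = lengths,
              genes_per_chromosome = genes_per_chromosome, grr = grr,
              n_families = n_families,
              n_tandem_families = n_tandem_families,
              family_size_p = family_size_p,
              fraction_ancient = fraction_ancient,
              p_transloc = p_transloc, dist_mean = dist_mean,
              nni_prob = nni_prob, collapse_prob = collapse_prob,
              rearrangements = rearrangements, inversions = inversions,
              n_shared_genes = n_shared_genes, jitter_sd = jitter_sd,
              hit_identity_mean = hit_identity_mean,
              hit_identity_sd = hit_identity_sd,
              decoy_prob = decoy_prob,
              decoy_identity_max = decoy_identity_max,
              n_tissues = n_tissues)
  cfg$n_tandem_families <- min(cfg$n_tandem_families, cfg$n_families)
  probs <- c(cfg$fraction_ancient, cfg$p_transloc, cfg$nni_prob,
             cfg$collapse_prob, cfg$decoy_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!is.null(grr) && any(grr$enrichment < 1))
    stop("GRR enrichment factors must be >= 1")
  class(cfg) <- "scenario_config"
  cfg
}

#' Simulate a genetic map with planted structure
#'
#' Background gene positions are uniform per chromosome. Each configured
#' gene-rich region adds (enrichment - 1) x background density x width
#' extra genes uniformly within its window. Dispersed families relabel
#' random background loci; planted tandem families add runs of closely
#' spaced same-family loci (consecutive gaps up to ~2.5 cM) on a single
#' chromosome.
#'
#' @param cfg a \code{\link{scenario_config}}.
#' @return list with \code{map} (a \code{\link{genetic_map}}) and
#'   \code{truth}: \code{grr} (regions), \code{grr_loci},
#'   \code{tandem_families}, \code{family_of} (named vector locus ->
#'   family).
#' @export
simulate_map <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  chrs <- names(cfg$lengths)
  npc <- rep(cfg$genes_per_chromosome, length.out = length(chrs))
  rows <- list()
  grr_loci <- character(0)
  counter <- 0L
  add_locus <- function(chr, pos, fam = NA_character_) {
    counter <<- counter + 1L
    data.frame(locus_id = sprintf("L%05d", counter),
               gene_id = sprintf("G%05d", counter),
               chromosome = chr, position_cM = pos,
               family_id = fam, species = "focal")
  }
  for (i in seq_along(chrs)) {
    L <- cfg$lengths[[i]]
    for (p in sort(stats::runif(npc[i], 0, L)))
      rows[[length(rows) + 1L]] <- add_locus(chrs[i], p)
    if (!is.null(cfg$grr)) {
      g <- cfg$grr[cfg$grr$chromosome == chrs[i], , drop = FALSE]
      for (j in seq_len(nrow(g))) {
        lo <- max(0, g$center[j] - g$width[j] / 2)
        hi <- min(L, g$center[j] + g$width[j] / 2)
        extra <- round((g$enrichment[j] - 1) * (npc[i] / L) * (hi - lo))
        for (p in stats::runif(extra, lo, hi)) {
          r <- add_locus(chrs[i], p)
          grr_loci <- c(grr_loci, r$locus_id)
          rows[[length(rows) + 1L]] <- r
        }
      }
    }
  }
  df <- do.call(rbind, rows)

  fam_sizes <- 2L + stats::rgeom(cfg$n_families, cfg$family_size_p)
  n_disp <- cfg$n_families - cfg$n_tandem_families
  fam_ids <- sprintf("F%03d", seq_len(cfg$n_families))
  # dispersed families: relabel random background loci anywhere on the map
  if (n_disp > 0) {
    need <- sum(fam_sizes[seq_len(n_disp)])
    avail <- which(is.na(df$family_id))
    pick <- sample(avail, min(need, length(avail)))
    df$family_id[pick] <-
      rep(fam_ids[seq_len(n_disp)], fam_sizes[seq_len(n_disp)])[
        seq_along(pick)]
  }
  # tandem families: contiguous runs added on one chromosome each
  tandem_ids <- character(0)
  if (cfg$n_tandem_families > 0) {
    for (t in seq_len(cfg$n_tandem_families)) {
      fid <- fam_ids[n_disp + t]
      tandem_ids <- c(tandem_ids, fid)
      # concentrated families carry >= 3 members: under a C-chromosome
      # null a 2-member family reaches an empirical p of ~1/C at best,
      # so single-chromosome concentration is only detectable from 3 up
      k <- max(3L, fam_sizes[n_disp + t])
      chr <- sample(chrs, 1)
      L <- cfg$lengths[[chr]]
      gaps <- stats::runif(k - 1L, 0.1, 2.5)
      start <- stats::runif(1, 0, max(L - sum(gaps), 1))
      pos <- start + cumsum(c(0, gaps))
      pos <- pmin(pos, L)
      for (p in pos)
        df[nrow(df) + 1L, ] <- add_locus(chr, p, fid)
    }
  }
  map <- genetic_map(df, cfg$lengths)
  truth <- list(
    grr = cfg$grr, grr_loci = grr_loci, tandem_families = tandem_ids,
    family_of = stats::setNames(df$family_id, df$locus_id))
  list(map = map, truth = truth)
}

# -- duplication-history tree generator ------------------------------------

.sim_leaf <- function(label) list(leaf = label)
.sim_node <- function(children, event = NA_character_)
  list(children = children, event = event)

.sim_newick <- function(node) {
  if (!is.null(node$leaf)) return(node$leaf)
  inner <- paste(vapply(node$children, .sim_newick, character(1)),
                 collapse = ",")
  paste0("(", inner, ")100")
}

.sim_focal_leaves <- function(node) {
  if (!is.null(node$leaf))
    return(if (startsWith(node$leaf, "Pg")) node$leaf else character(0))
  unlist(lapply(node$children, .sim_focal_leaves))
}

#' Simulate gene-family trees with a known duplication history
#'
#' For each family, k focal gene copies coalesce backwards in time;
#' events earlier than the GA split are "recent", later ones "ancient"
#' (the number of recent events is binomial with success probability
#' 1 - \code{fraction_ancient}). Every lineage crossing the GA split
#' receives a pine sister leaf and an angiosperm sister cherry (one
#' Arabidopsis-type and one rice-type leaf), so ancient duplications are
#' separated by intervening angiosperm lineages and recent ones are not.
#' Focal genes are placed on a map: at each duplication one copy keeps
#' its parent's location and the other is translocated to a random other
#' chromosome with the class's probability, or otherwise offset by an
#' exponential same-chromosome distance (mean per class, truncated to
#' the chromosome). The NJ-like and MP-like emitted trees are
#' independently degraded copies of the true topology (NNI moves, split
#' collapsing); retained splits carry support 100.
#'
#' @param cfg a \code{\link{scenario_config}}.
#' @return list with \code{nj}, \code{mp} (named lists of
#'   \code{support_tree}), \code{map} (a \code{\link{genetic_map}} of the
#'   focal genes), and \code{truth}: \code{pairs} (family_id, gene_a,
#'   gene_b, age, same_chromosome, distance), \code{events} (per
#'   duplication: family_id, age, translocated, distance).
#' @export
simulate_family_trees <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  chrs <- names(cfg$lengths)
  fam_sizes <- 2L + stats::rgeom(cfg$n_families, cfg$family_size_p)
  fam_ids <- sprintf("F%03d", seq_len(cfg$n_families))
  nj <- list(); mp <- list()
  loci <- list(); truth_pairs <- list(); truth_events <- list()

  for (f in seq_along(fam_ids)) {
    k <- fam_sizes[f]
    genes <- sprintf("Pg%03d-%02d", f, seq_len(k))
    lineages <- lapply(genes, .sim_leaf)
    ages <- list()  # per join node, in construction order
    n_recent <- stats::rbinom(1, k - 1L, 1 - cfg$fraction_ancient)
    # recent joins first (more recent in time), then ancient joins
    for (j in seq_len(n_recent)) {
      pick <- sample(length(lineages), 2)
      joined <- .sim_node(lineages[pick], event = "recent")
      lineages <- c(lineages[-pick], list(joined))
    }
    # lineages now crossing the GA split: wrap with pine + angiosperms
    lineages <- lapply(seq_along(lineages), function(i)
      .sim_node(list(
        .sim_node(list(lineages[[i]],
                       .sim_leaf(sprintf("Pt%03d-%02d", f, i)))),
        .sim_node(list(.sim_leaf(sprintf("AT%03d-%02d", f, i)),
                       .sim_leaf(sprintf("Os%03d-%02d", f, i))))),
        event = "speciation"))
    while (length(lineages) > 1L) {
      pick <- sample(length(lineages), 2)
      joined <- .sim_node(lineages[pick], event = "ancient")
      lineages <- c(lineages[-pick], list(joined))
    }
    root <- lineages[[1]]

    # map placement by recursion over duplication nodes
    fam_rows <- list()
    fam_events <- list()
    place <- function(node, chr, pos) {
      if (!is.null(node$leaf)) {
        if (startsWith(node$leaf, "Pg"))
          fam_rows[[length(fam_rows) + 1L]] <<- data.frame(
            locus_id = paste0("loc_", node$leaf), gene_id = node$leaf,
            chromosome = chr, position_cM = pos,
            family_id = fam_ids[f], species = "focal")
        return(invisible(NULL))
      }
      if (identical(node$event, "speciation")) {
        # descend into the gymnosperm side only; first child of the
        # wrap is (lineage, pine), whose first child is the lineage
        place(node$children[[1]]$children[[1]], chr, pos)
        return(invisible(NULL))
      }
      # duplication node: child 1 inherits, child 2 moves
      cl <- node$event
      place(node$children[[1]], chr, pos)
      if (stats::runif(1) < cfg$p_transloc[[cl]]) {
        new_chr <- sample(setdiff(chrs, chr), 1)
        new_pos <- stats::runif(1, 0, cfg$lengths[[new_chr]])
        fam_events[[length(fam_events) + 1L]] <<- data.frame(
          family_id = fam_ids[f], age = cl, translocated = TRUE,
          distance = NA_real_)
        place(node$children[[2]], new_chr, new_pos)
      } else {
        L <- cfg$lengths[[chr]]
        repeat { d <- stats::rexp(1, 1 / cfg$dist_mean[[cl]]); if (d < L) break }
        dir <- sample(c(-1, 1), 1)
        new_pos <- pos + dir * d
        if (new_pos < 0 || new_pos > L) new_pos <- pos - dir * d
        if (new_pos < 0 || new_pos > L)
          new_pos <- stats::runif(1, max(0, pos - d), min(L, pos + d))
        fam_events[[length(fam_events) + 1L]] <<- data.frame(
          family_id = fam_ids[f], age = cl, translocated = FALSE,
          distance = abs(new_pos - pos))
        place(node$children[[2]], chr, new_pos)
      }
      invisible(NULL)
    }
    chr0 <- sample(chrs, 1)
    place(root, chr0, stats::runif(1, 0, cfg$lengths[[chr0]]))
    fam_loci <- do.call(rbind, fam_rows)
    loci[[f]] <- fam_loci
    if (length(fam_events))
      truth_events[[f]] <- do.call(rbind, fam_events)

    # pair-level truth: MRCA event class per focal pair
    mrca_age <- function(node, a, b) {
      if (!is.null(node$leaf)) return(NULL)
      for (ch in node$children) {
        lv <- .sim_focal_leaves(ch)
        if (a %in% lv && b %in% lv) return(mrca_age(ch, a, b))
      }
      node$event
    }
    prs <- utils::combn(genes, 2L)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      age <- mrca_age(root, a, b)
      if (identical(age, "speciation")) age <- "ancient"  # defensive
      pa <- fam_loci[match(a, fam_loci$gene_id), ]
      pb <- fam_loci[match(b, fam_loci$gene_id), ]
      truth_pairs[[length(truth_pairs) + 1L]] <- data.frame(
        family_id = fam_ids[f], gene_a = a, gene_b = b, age = age,
        same_chromosome = pa$chromosome == pb$chromosome,
        distance = if (pa$chromosome == pb$chromosome)
          abs(pa$position_cM - pb$position_cM) else NA_real_)
    }

    true_tree <- ape::read.tree(text = paste0(.sim_newick(root), ";"))
    nj[[fam_ids[f]]] <- .noisy_copy(true_tree, cfg)
    mp[[fam_ids[f]]] <- .noisy_copy(true_tree, cfg)
  }
  map <- genetic_map(do.call(rbind, loci), cfg$lengths)
  list(nj = nj, mp = mp, map = map,
       truth = list(pairs = do.call(rbind, truth_pairs),
                    events = do.call(rbind, truth_events)))
}

# one independently degraded copy of the true family tree
.noisy_copy <- function(true_tree, cfg) {
  tr <- true_tree
  n_internal <- tr$Nnode - 1L
  if (cfg$nni_prob > 0 && n_internal > 0) {
    moves <- stats::rbinom(1, n_internal, cfg$nni_prob)
    if (moves > 0) tr <- phangorn::rNNI(tr, moves = moves)
  }
  st <- as_support_tree(tr)
  st$supports <- rep(100, length(st$splits))
  if (cfg$collapse_prob > 0 && length(st$splits)) {
    keep <- stats::runif(length(st$splits)) >= cfg$collapse_prob
    st <- support_tree(st$labels, st$splits[keep], st$supports[keep],
                       st$classes)
  }
  st
}

#' Simulate a pair of homologous genetic maps with hit tables
#'
#' Map B is derived from map A by relabelling chromosomes, jittering
#' positions, translocating \code{rearrangements} random single genes to
#' other chromosomes and reversing \code{inversions} random segments.
#' Reciprocal hit tables contain every true ortholog at an identity drawn
#' from a truncated normal, plus decoy hits capped below the usual RBH
#' identity threshold.
#'
#' @param cfg a \code{\link{scenario_config}}.
#' @return list with \code{map_a}, \code{map_b}, \code{ab}, \code{ba}
#'   (hit tables) and \code{truth}: \code{orthologs} (gene_a, gene_b),
#'   \code{homoeology} (chr_a -> chr_b), \code{translocated} (gene_a ids
#'   moved in B).
#' @export
simulate_map_pair <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  chrs_a <- names(cfg$lengths)
  chrs_b <- paste0("p", chrs_a)
  lengths_b <- stats::setNames(cfg$lengths, chrs_b)
  n <- cfg$n_shared_genes
  chr_idx <- sample(seq_along(chrs_a), n, replace = TRUE,
                    prob = cfg$lengths / sum(cfg$lengths))
  pos_a <- stats::runif(n, 0, cfg$lengths[chr_idx])
  a <- data.frame(locus_id = sprintf("la%04d", seq_len(n)),
                  gene_id = sprintf("gA%04d", seq_len(n)),
                  chromosome = chrs_a[chr_idx], position_cM = pos_a,
                  family_id = NA_character_, species = "focal")
  pos_b <- pmin(pmax(pos_a + stats::rnorm(n, 0, cfg$jitter_sd), 0),
                cfg$lengths[chr_idx])
  b <- data.frame(locus_id = sprintf("lb%04d", seq_len(n)),
                  gene_id = sprintf("gB%04d", seq_len(n)),
                  chromosome = chrs_b[chr_idx], position_cM = pos_b,
                  family_id = NA_character_, species = "donor")
  translocated <- character(0)
  if (cfg$rearrangements > 0) {
    mv <- sample(n, min(cfg$rearrangements, n))
    for (i in mv) {
      new_chr <- sample(setdiff(chrs_b, b$chromosome[i]), 1)
      b$chromosome[i] <- new_chr
      b$position_cM[i] <- stats::runif(1, 0, lengths_b[[new_chr]])
    }
    translocated <- a$gene_id[mv]
  }
  if (cfg$inversions > 0) {
    for (j in seq_len(cfg$inversions)) {
      chr <- sample(chrs_b, 1)
      on_chr <- which(b$chromosome == chr)
      if (length(on_chr) < 3L) next
      L <- lengths_b[[chr]]
      w <- stats::runif(1, 0.2 * L, 0.6 * L)
      s <- stats::runif(1, 0, L - w)
      inside <- on_chr[b$position_cM[on_chr] >= s &
                         b$position_cM[on_chr] <= s + w]
      b$position_cM[inside] <- s + (s + w) - b$position_cM[inside]
    }
  }
  ident <- pmin(pmax(stats::rnorm(n, cfg$hit_identity_mean,
                                  cfg$hit_identity_sd), 70), 100)
  ab <- data.frame(qseqid = a$gene_id, sseqid = b$gene_id,
                   pident = ident, bitscore = round(ident * 10))
  ba <- data.frame(qseqid = b$gene_id, sseqid = a$gene_id,
                   pident = ident, bitscore = round(ident * 10))
  n_decoy <- stats::rbinom(1, n, cfg$decoy_prob)
  if (n_decoy > 0) {
    qi <- sample(n, n_decoy, replace = TRUE)
    si <- vapply(qi, function(i) sample(setdiff(seq_len(n), i), 1),
                 integer(1))
    di <- stats::runif(n_decoy, 70, cfg$decoy_identity_max)
    ab <- rbind(ab, data.frame(qseqid = a$gene_id[qi],
                               sseqid = b$gene_id[si], pident = di,
                               bitscore = round(di * 10)))
    ba <- rbind(ba, data.frame(qseqid = b$gene_id[qi],
                               sseqid = a$gene_id[si], pident = di,
                               bitscore = round(di * 10)))
  }
  list(map_a = genetic_map(a, cfg$lengths),
       map_b = genetic_map(b, lengths_b),
       ab = ab, ba = ba,
       truth = list(orthologs = data.frame(gene_a = a$gene_id,
                                           gene_b = b$gene_id),
                    homoeology = stats::setNames(chrs_b, chrs_a),
                    translocated = translocated))
}

#' Simulate a gene-by-tissue expression matrix
#'
#' Genes in co-regulated groups share a latent tissue profile plus
#' independent noise; all other genes are independent standard normal.
#'
#' @param genes gene ids (rownames of the result).
#' @param groups list of character vectors (co-regulated gene groups).
#' @param n_tissues number of tissues.
#' @param noise_sd within-group noise standard deviation.
#' @param seed RNG seed.
#' @return numeric matrix, genes x tissues.
#' @export
simulate_expression <- function(genes, groups = list(), n_tissues = 8,
                                noise_sd = 0.2, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(length(genes) * n_tissues),
              nrow = length(genes),
              dimnames = list(genes, paste0("tissue", seq_len(n_tissues))))
  for (g in groups) {
    latent <- stats::rnorm(n_tissues)
    for (gene in intersect(g, genes))
      m[gene, ] <- latent + stats::rnorm(n_tissues, 0, noise_sd)
  }
  m
}
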