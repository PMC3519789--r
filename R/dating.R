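# Dating gene duplications against the gymnosperm-angiosperm (GA) split.
#
# The temporal reference is topological: on a gene-family tree containing
# angiosperm sequences, a duplication node separating two focal-gymnosperm
# gene copies with no intervening angiosperm lineage must postdate the GA
# split (recent); intervening angiosperm lineages on the path place the
# duplication before the split (ancient). Polytomies that leave the
# angiosperm placement ambiguous yield "undetermined".

.rooted_clades <- function(st, root_leaf_idx) {
  # re-express every split as the side not containing the root leaf
  n <- length(st$labels)
  lapply(st$splits, function(s)
    if (root_leaf_idx %in% s) setdiff(seq_len(n), s) else s)
}

#' Classify one focal gene pair as recent, ancient or undetermined
#'
#' Splits supported below \code{min_support} are collapsed first. The tree
#' is then rooted on the lexicographically smallest angiosperm leaf and
#' the clade of the most recent common ancestor (MRCA) of the two focal
#' genes is examined: if it contains no angiosperm leaf the duplication is
#' \code{"recent"} (postdates the GA split); if an angiosperm lies inside
#' the MRCA child holding either gene (or the MRCA is binary) the
#' duplication is \code{"ancient"}; if the MRCA is a multifurcation whose
#' angiosperm leaves all sit in other children, the placement is
#' ambiguous and the pair is \code{"undetermined"}.
#'
#' @param tree a \code{support_tree} (or \code{phylo}).
#' @param a,b labels of the two focal-gymnosperm leaves.
#' @param min_support percent support below which splits are collapsed.
#' @param classes prefix table used when converting \code{phylo} input.
#' @param root_on override the rooting choice with a specific angiosperm
#'   leaf label (the label must be an angiosperm). Recent/ancient calls
#'   are root-invariant; only polytomy-ambiguous cases can differ.
#' @return one of \code{"recent"}, \code{"ancient"},
#'   \code{"undetermined"}.
#' @export
classify_pair_age <- function(tree, a, b, min_support = 50,
                              classes = default_prefix_table(),
                              root_on = NULL) {
  st <- as_support_tree(tree, classes)
  st <- collapse_splits(st, min_support)
  n <- length(st$labels)
  ang <- which(st$classes == "angiosperm")
  if (!length(ang))
    stop("family not anchored to the GA reference: no angiosperm leaf")
  ia <- match(a, st$labels); ib <- match(b, st$labels)
  if (is.na(ia) || is.na(ib))
    stop("pair leaves absent from tree: ",
         paste(c(a, b)[c(is.na(ia), is.na(ib))], collapse = ", "))
  if (ia == ib) stop("a pair needs two distinct leaves")
  root <- if (is.null(root_on)) {
    ang[1L]  # labels are stored sorted: first angiosperm index is the
             # lexicographically smallest angiosperm label
  } else {
    r <- match(root_on, st$labels)
    if (is.na(r) || !(r %in% ang))
      stop("root_on must name an angiosperm leaf of the tree")
    r
  }
  clades <- .rooted_clades(st, root)
  ingroup <- setdiff(seq_len(n), root)

  # MRCA clade: smallest clade containing both a and b (root node if none)
  holds <- vapply(clades, function(cl) ia %in% cl && ib %in% cl, logical(1))
  mrca <- if (any(holds)) {
    sizes <- vapply(clades, length, integer(1))
    clades[[which(holds)[which.min(sizes[holds])]]]
  } else ingroup

  if (!any(mrca %in% ang)) return("recent")

  # children of the MRCA node: maximal proper subclades + leftover leaves
  proper <- clades[vapply(clades, function(cl)
    length(cl) < length(mrca) && all(cl %in% mrca), logical(1))]
  children <- list()
  covered <- integer(0)
  if (length(proper)) {
    ord <- order(-vapply(proper, length, integer(1)))
    for (k in ord) {
      cl <- proper[[k]]
      if (!any(cl %in% covered)) {
        children[[length(children) + 1L]] <- cl
        covered <- c(covered, cl)
      }
    }
  }
  for (leaf in setdiff(mrca, covered))
    children[[length(children) + 1L]] <- leaf

  in_a <- vapply(children, function(cl) ia %in% cl, logical(1))
  in_b <- vapply(children, function(cl) ib %in% cl, logical(1))
  c_a <- children[[which(in_a)]]
  c_b <- children[[which(in_b)]]
  if (any(c(c_a, c_b) %in% ang)) return("ancient")
  if (length(children) == 2L) return("ancient")
  "undetermined"
}

#' Classify all mapped gene pairs of every family from NJ and MP trees
#'
#' Each family contributes all C(k, 2) pairs among its k mapped focal
#' genes. A pair is classified independently on the family's NJ and MP
#' consensus trees (\code{\link{classify_pair_age}}); the final label is
#' the shared one, or \code{"incongruent"} when the two trees disagree (or
#' a gene is missing from one tree). The strict consensus tree of each
#' family is also produced.
#'
#' @param nj,mp named lists (by family id) of \code{support_tree}; names
#'   must match.
#' @param map a \code{\link{genetic_map}}; focal leaves are matched to
#'   loci by gene id.
#' @param min_support collapse threshold (percent).
#' @return object of class \code{pair_age_calls}: list with \code{pairs}
#'   (data.frame: family_id, gene_a, gene_b, chr_a, pos_a, chr_b, pos_b,
#'   label_nj, label_mp, label), \code{tally} (named counts: total,
#'   congruent, incongruent, ancient, recent, undetermined),
#'   \code{percentages} (of congruent pairs), and \code{consensus} (named
#'   list of strict consensus trees).
#' @export
classify_families <- function(nj, mp, map, min_support = 50) {
  stopifnot(inherits(map, "genetic_map"))
  fams <- names(nj)
  if (!identical(sort(fams), sort(names(mp))))
    stop("NJ and MP tree sets cover different families")
  loci <- map$loci
  rows <- list()
  consensus <- list()
  for (fam in fams) {
    tnj <- nj[[fam]]; tmp_ <- mp[[fam]]
    consensus[[fam]] <- strict_consensus(tnj, tmp_)
    fam_loci <- loci[!is.na(loci$family_id) & loci$family_id == fam, ,
                     drop = FALSE]
    focal_nj <- tnj$labels[tnj$classes == "focal_gymno"]
    mapped <- fam_loci$gene_id[fam_loci$gene_id %in%
                                 union(focal_nj,
                                       tmp_$labels[tmp_$classes == "focal_gymno"])]
    mapped <- sort(unique(mapped))
    if (length(mapped) < 2L) next
    prs <- utils::combn(mapped, 2L)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      lab1 <- if (all(c(a, b) %in% tnj$labels))
        classify_pair_age(tnj, a, b, min_support) else NA_character_
      lab2 <- if (all(c(a, b) %in% tmp_$labels))
        classify_pair_age(tmp_, a, b, min_support) else NA_character_
      final <- if (is.na(lab1) || is.na(lab2) || lab1 != lab2)
        "incongruent" else lab1
      ra <- fam_loci[match(a, fam_loci$gene_id), ]
      rb <- fam_loci[match(b, fam_loci$gene_id), ]
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = fam, gene_a = a, gene_b = b,
        chr_a = ra$chromosome, pos_a = ra$position_cM,
        chr_b = rb$chromosome, pos_b = rb$position_cM,
        label_nj = lab1, label_mp = lab2, label = final)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(), gene_a = character(),
               gene_b = character(), chr_a = character(),
               pos_a = numeric(), chr_b = character(), pos_b = numeric(),
               label_nj = character(), label_mp = character(),
               label = character())
  tally <- c(total = nrow(pairs),
             congruent = sum(pairs$label != "incongruent"),
             incongruent = sum(pairs$label == "incongruent"),
             ancient = sum(pairs$label == "ancient"),
             recent = sum(pairs$label == "recent"),
             undetermined = sum(pairs$label == "undetermined"))
  structure(list(pairs = pairs, tally = tally,
                 percentages = age_percentages(tally["ancient"],
                                               tally["recent"],
                                               tally["undetermined"]),
                 consensus = consensus),
            class = "pair_age_calls")
}

#' Percentages and ancient:recent ratio from age tallies
#'
#' @param ancient,recent,undetermined congruent-pair counts.
#' @return named vector: \code{pct_ancient}, \code{pct_recent},
#'   \code{pct_undetermined} (percent of congruent pairs, one decimal
#'   precision retained in full), and \code{ratio_ancient_recent}.
#' @export
age_percentages <- function(ancient, recent, undetermined) {
  ancient <- unname(ancient); recent <- unname(recent)
  undetermined <- unname(undetermined)
  total <- ancient + recent + undetermined
  if (total == 0)
    return(c(pct_ancient = NA_real_, pct_recent = NA_real_,
             pct_undetermined = NA_real_, ratio_ancient_recent = NA_real_))
  c(pct_ancient = 100 * ancient / total,
    pct_recent = 100 * recent / total,
    pct_undetermined = 100 * undetermined / total,
    ratio_ancient_recent = if (recent > 0) ancient / recent else Inf)
}

#' @export
print.pair_age_calls <- function(x, ...) {
  t <- x$tally
  cat(sprintf("Gene-pair duplication dating: %d pairs from %d families\n",
              t[["total"]], length(x$consensus)))
  cat(sprintf("  congruent %d (%.1f%%), incongruent %d (%.1f%%)\n",
              t[["congruent"]], 100 * t[["congruent"]] / max(t[["total"]], 1),
              t[["incongruent"]],
              100 * t[["incongruent"]] / max(t[["total"]], 1)))
  p <- x$percentages
  cat(sprintf("  of congruent: ancient %d (%.1f%%), recent %d (%.1f%%), undetermined %d (%.1f%%)\n",
              t[["ancient"]], p[["pct_ancient"]],
              t[["recent"]], p[["pct_recent"]],
              t[["undetermined"]], p[["pct_undetermined"]]))
  if (is.finite(p[["ratio_ancient_recent"]]))
    cat(sprintf("  ancient:recent ratio = %.1f : 1\n",
                p[["ratio_ancient_recent"]]))
  invisible(x)
}
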