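# Bipartition algebra for leaf-labelled unrooted trees.
#
# A support_tree stores a tree as its set of non-trivial bipartitions
# (splits): labels are kept sorted, and every split is represented by the
# side NOT containing the first label, as a sorted integer vector of leaf
# indices. Two splits canonicalized this way are compatible iff the sides
# nest or are disjoint, which makes consensus operations set algebra.

#' Default leaf-label prefix to taxon-class table
#'
#' Focal gymnosperm (spruce, "Pg"), other gymnosperm (pine, "Pt"),
#' angiosperms (Arabidopsis "AT", rice "Os").
#' @export
default_prefix_table <- function() {
  c(Pg = "focal_gymno", Pt = "other_gymno",
    AT = "angiosperm", Os = "angiosperm")
}

.classify_leaves <- function(labels, prefix_table) {
  prefixes <- names(prefix_table)
  out <- character(length(labels))
  for (i in seq_along(labels)) {
    hit <- prefixes[startsWith(labels[i], prefixes)]
    if (!length(hit))
      stop("leaf label '", labels[i],
           "' matches no prefix in the taxon-class table")
    out[i] <- prefix_table[[hit[which.max(nchar(hit))]]]
  }
  out
}

.canonical_split <- function(side, n) {
  side <- sort(unique(side))
  if (1L %in% side) side <- setdiff(seq_len(n), side)
  side
}

.split_key <- function(side) paste(side, collapse = ",")

#' Construct a support tree from its splits
#'
#' @param labels leaf labels (any order; stored sorted).
#' @param splits list of integer vectors: for each internal edge, the leaf
#'   indices (into the sorted labels) on one side.
#' @param supports numeric vector of supports in \code{[0, 100]} (NA =
#'   unannotated), parallel to \code{splits}.
#' @param classes taxon class per leaf (parallel to sorted labels), or a
#'   prefix table (named character vector prefix -> class) used to derive
#'   them.
#' @return object of class \code{support_tree}.
#' @export
support_tree <- function(labels, splits = list(), supports = numeric(),
                         classes = default_prefix_table()) {
  ord <- order(labels)
  labels <- labels[ord]
  if (anyDuplicated(labels)) stop("leaf labels must be unique")
  n <- length(labels)
  if (length(classes) && !is.null(names(classes)) &&
      !length(setdiff(names(classes), labels)) == 0) {
    classes <- .classify_leaves(labels, classes)
  } else if (length(classes) == n && is.null(names(classes))) {
    classes <- classes[ord]
  } else {
    classes <- .classify_leaves(labels, classes)
  }
  splits <- lapply(splits, .canonical_split, n = n)
  keep <- vapply(splits, function(s)
    length(s) >= 2L && length(s) <= n - 2L, logical(1))
  splits <- splits[keep]
  supports <- if (length(supports)) supports[keep] else
    rep(NA_real_, length(splits))
  keys <- vapply(splits, .split_key, character(1))
  if (anyDuplicated(keys)) {
    first <- !duplicated(keys)
    supports <- vapply(unique(keys), function(k) {
      v <- supports[keys == k]
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    }, numeric(1))
    splits <- splits[first]
  }
  st <- structure(list(labels = labels, classes = classes,
                       splits = splits, supports = unname(supports)),
                  class = "support_tree")
  .check_compatible(st)
  st
}

.splits_compatible <- function(a, b) {
  # both canonical (exclude leaf 1): compatible iff nested or disjoint
  inter <- length(intersect(a, b))
  inter == 0L || inter == length(a) || inter == length(b)
}

.check_compatible <- function(st) {
  s <- st$splits
  if (length(s) < 2L) return(invisible(TRUE))
  for (i in seq_len(length(s) - 1L))
    for (j in (i + 1L):length(s))
      if (!.splits_compatible(s[[i]], s[[j]]))
        stop("incompatible splits within one tree")
  invisible(TRUE)
}

#' Convert an ape phylo tree to a support tree
#'
#' Internal node labels are read as bootstrap supports when numeric.
#'
#' @param tree an \code{ape::phylo} object.
#' @param classes taxon classes or a prefix table (see
#'   \code{\link{support_tree}}).
#' @return a \code{support_tree}.
#' @export
as_support_tree <- function(tree, classes = default_prefix_table()) {
  if (inherits(tree, "support_tree")) return(tree)
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  labels <- sort(tree$tip.label)
  idx_of_tip <- match(tree$tip.label, labels)
  tr <- stats::reorder(tree, "postorder")
  nnode <- tr$Nnode
  tips_of <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) tips_of[[i]] <- idx_of_tip[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    tips_of[[p]] <- c(tips_of[[p]], tips_of[[ch]])
  }
  root <- ntip + 1L
  internal <- setdiff(unique(tr$edge[, 2]), seq_len(ntip))
  splits <- lapply(internal, function(nd) tips_of[[nd]])
  supports <- rep(NA_real_, length(internal))
  if (!is.null(tr$node.label)) {
    lab <- tr$node.label[internal - ntip]
    supports <- suppressWarnings(as.numeric(lab))
  }
  support_tree(labels, splits, supports, classes)
}

#' @export
print.support_tree <- function(x, ...) {
  cat(sprintf("Support tree: %d leaves (%s), %d internal splits\n",
              length(x$labels),
              paste(sprintf("%d %s", table(x$classes),
                            names(table(x$classes))), collapse = ", "),
              length(x$splits)))
  cat(" ", to_newick(x), "\n")
  invisible(x)
}

#' Render a support tree as a Newick string
#'
#' The tree is written rooted at its first (sorted) leaf's attachment
#' node; supports appear as internal node labels.
#'
#' @param st a \code{support_tree}.
#' @return Newick string (with trailing semicolon).
#' @export
to_newick <- function(st) {
  n <- length(st$labels)
  clades <- st$splits  # all exclude leaf 1
  sizes <- vapply(clades, length, integer(1))
  ord <- order(-sizes)
  render <- function(members, avail) {
    # avail: indices (into clades) of splits that are subsets of members
    parts <- character(0)
    used <- logical(length(st$labels))
    for (k in avail) {
      cl <- clades[[k]]
      if (any(used[cl])) next  # contained in an already-rendered child
      sub_avail <- avail[vapply(avail, function(j)
        !identical(j, k) && all(clades[[j]] %in% cl), logical(1))]
      sup <- st$supports[k]
      lab <- if (is.na(sup)) "" else format(sup, trim = TRUE)
      parts <- c(parts, paste0(render(cl, sub_avail), lab))
      used[cl] <- TRUE
    }
    singles <- members[!used[members]]
    parts <- c(parts, st$labels[singles])
    paste0("(", paste(parts, collapse = ","), ")")
  }
  ingroup <- setdiff(seq_len(n), 1L)
  avail <- ord[vapply(ord, function(k)
    all(clades[[k]] %in% ingroup), logical(1))]
  paste0("(", st$labels[1], ",",
         paste0(render(ingroup, avail)), ");")
}

#' @export
as.phylo.support_tree <- function(x, ...) ape::read.tree(text = to_newick(x))

#' Read a set of support trees from a Newick file
#'
#' Supports are taken from internal node labels; taxon classes are derived
#' from the label-prefix table.
#'
#' @param path Newick file (one or more trees).
#' @param classes prefix table, default \code{\link{default_prefix_table}}.
#' @return list of \code{support_tree}.
#' @export
read_tree_set <- function(path, classes = default_prefix_table()) {
  trees <- ape::read.tree(path)
  if (is.null(trees)) stop("malformed Newick in ", path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(trees, as_support_tree, classes = classes)
}

#' Write support trees to a Newick file
#'
#' @param trees a \code{support_tree} or list of them.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_tree_set <- function(trees, path) {
  if (inherits(trees, "support_tree")) trees <- list(trees)
  writeLines(vapply(trees, to_newick, character(1)), path)
  invisible(path)
}

.same_leaves <- function(trees) {
  labs <- lapply(trees, `[[`, "labels")
  all(vapply(labs[-1], identical, logical(1), labs[[1]]))
}

#' Majority-rule consensus of a tree set
#'
#' Returns the tree containing exactly the splits present in strictly more
#' than half of the input trees (such splits are mutually compatible),
#' each annotated with its percentage occurrence as support. All other
#' nodes collapse to polytomies. Splits at exactly 50% are excluded.
#'
#' @param trees list of \code{support_tree} (or \code{phylo}) on one leaf
#'   set.
#' @param classes prefix table used when converting \code{phylo} inputs.
#' @return a \code{support_tree}.
#' @export
majority_rule_consensus <- function(trees, classes = default_prefix_table()) {
  trees <- lapply(trees, as_support_tree, classes = classes)
  if (!length(trees)) stop("empty tree set")
  if (!.same_leaves(trees)) stop("trees have mismatched leaf sets")
  N <- length(trees)
  keys <- unlist(lapply(trees, function(t)
    vapply(t$splits, .split_key, character(1))))
  if (!length(keys))
    return(support_tree(trees[[1]]$labels, list(), numeric(),
                        trees[[1]]$classes))
  tab <- table(keys)
  kept <- names(tab)[tab / N > 0.5]
  splits <- lapply(kept, function(k)
    as.integer(strsplit(k, ",", fixed = TRUE)[[1]]))
  supports <- 100 * as.numeric(tab[kept]) / N
  support_tree(trees[[1]]$labels, splits, supports, trees[[1]]$classes)
}

#' Strict consensus of two trees
#'
#' The tree whose split set is the intersection of the two inputs' split
#' sets; each retained split carries the smaller of its two supports.
#'
#' @param t1,t2 \code{support_tree} (or \code{phylo}) on one leaf set.
#' @param classes prefix table used when converting \code{phylo} inputs.
#' @return a \code{support_tree}.
#' @export
strict_consensus <- function(t1, t2, classes = default_prefix_table()) {
  t1 <- as_support_tree(t1, classes); t2 <- as_support_tree(t2, classes)
  if (!identical(t1$labels, t2$labels))
    stop("trees have mismatched leaf sets")
  k1 <- vapply(t1$splits, .split_key, character(1))
  k2 <- vapply(t2$splits, .split_key, character(1))
  common <- intersect(k1, k2)
  splits <- t1$splits[match(common, k1)]
  supports <- pmin(t1$supports[match(common, k1)],
                   t2$supports[match(common, k2)], na.rm = FALSE)
  support_tree(t1$labels, splits, supports, t1$classes)
}

#' Collapse weakly supported splits
#'
#' Removes splits whose support is below \code{min_support} percent;
#' splits with missing support are retained.
#'
#' @param st a \code{support_tree}.
#' @param min_support percent threshold.
#' @return a \code{support_tree}.
#' @export
collapse_splits <- function(st, min_support = 50) {
  keep <- is.na(st$supports) | st$supports >= min_support
  support_tree(st$labels, st$splits[keep], st$supports[keep], st$classes)
}
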