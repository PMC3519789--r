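#' Construct a genetic map
#'
#' A genetic map is an ordered set of linkage groups ("chromosomes"), each
#' with a length in centiMorgans, carrying gene loci at cM positions.
#' Positions live on the half-open interval \code{[0, length)}; ties are
#' allowed (zero-recombinant loci print at identical positions).
#'
#' @param loci data.frame with columns \code{locus_id}, \code{gene_id},
#'   \code{chromosome}, \code{position_cM} and optionally \code{family_id}
#'   and \code{species}. \code{family_id} may be \code{NA} for genes not
#'   assigned to a family.
#' @param lengths named numeric vector of chromosome lengths (cM); names are
#'   the chromosome labels and fix the chromosome order.
#' @return an object of class \code{genetic_map}: a list with elements
#'   \code{chromosomes}, \code{lengths} and \code{loci}.
#' @export
genetic_map <- function(loci, lengths) {
  stopifnot(is.data.frame(loci), is.numeric(lengths))
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("'lengths' must be a named vector of chromosome lengths")
  if (any(lengths <= 0)) stop("chromosome lengths must be > 0")
  required <- c("locus_id", "gene_id", "chromosome", "position_cM")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols))
    stop("missing map columns: ", paste(missing_cols, collapse = ", "))
  if (!"family_id" %in% names(loci)) loci$family_id <- NA_character_
  if (!"species" %in% names(loci)) loci$species <- "focal"
  loci$locus_id <- as.character(loci$locus_id)
  loci$gene_id <- as.character(loci$gene_id)
  loci$chromosome <- as.character(loci$chromosome)
  loci$family_id <- as.character(loci$family_id)
  loci$species <- as.character(loci$species)
  loci$position_cM <- as.numeric(loci$position_cM)
  loci <- loci[, c(required, "family_id", "species")]

  if (anyDuplicated(loci$locus_id))
    stop("duplicate locus ids: ",
         paste(unique(loci$locus_id[duplicated(loci$locus_id)]), collapse = ", "))
  bad_chr <- setdiff(unique(loci$chromosome), names(lengths))
  if (length(bad_chr))
    stop("loci on undeclared chromosomes: ", paste(bad_chr, collapse = ", "))
  if (any(is.na(loci$position_cM)))
    stop("non-numeric locus positions")
  len_of <- lengths[loci$chromosome]
  out_of_range <- loci$position_cM < 0 | loci$position_cM > len_of
  if (any(out_of_range))
    stop("locus positions outside [0, length]: ",
         paste(loci$locus_id[out_of_range], collapse = ", "))

  loci <- loci[order(match(loci$chromosome, names(lengths)),
                     loci$position_cM, loci$locus_id), , drop = FALSE]
  rownames(loci) <- NULL
  structure(
    list(chromosomes = names(lengths), lengths = lengths, loci = loci),
    class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map:", length(x$chromosomes), "linkage groups,",
      nrow(x$loci), "loci,",
      sprintf("%.1f cM total\n", sum(x$lengths)))
  tab <- table(factor(x$loci$chromosome, levels = x$chromosomes))
  df <- data.frame(chromosome = x$chromosomes,
                   length_cM = unname(x$lengths),
                   n_loci = as.integer(tab))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.genetic_map <- function(object, ...) {
  tab <- table(factor(object$loci$chromosome, levels = object$chromosomes))
  data.frame(chromosome = object$chromosomes,
             length_cM = unname(object$lengths),
             n_loci = as.integer(tab),
             density = as.integer(tab) / unname(object$lengths))
}

#' Read a genetic map from TSV
#'
#' Expects a header with columns \code{locus_id}, \code{gene_id},
#' \code{chromosome}, \code{position_cM} and optionally \code{family_id},
#' \code{species}. Chromosome lengths are supplied separately, or taken as
#' the per-chromosome position maxima when omitted.
#'
#' @param path TSV file path.
#' @param lengths named numeric vector of chromosome lengths (cM), or
#'   \code{NULL} to infer from the data.
#' @return a \code{\link{genetic_map}}.
#' @export
read_map_tsv <- function(path, lengths = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           na.strings = c("NA", ""))
  required <- c("locus_id", "gene_id", "chromosome", "position_cM")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("map file ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  pos <- suppressWarnings(as.numeric(raw$position_cM))
  if (any(is.na(pos) & !is.na(raw$position_cM)))
    stop("unparseable position at line ",
         which(is.na(pos) & !is.na(raw$position_cM))[1] + 1L, " of ", path)
  raw$position_cM <- pos
  if (is.null(lengths)) {
    lengths <- tapply(raw$position_cM, raw$chromosome, max)
    lengths <- stats::setNames(as.numeric(lengths), names(lengths))
  }
  genetic_map(raw, lengths)
}

#' Write a genetic map to TSV
#'
#' @param map a \code{\link{genetic_map}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_map_tsv <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  utils::write.table(map$loci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Transfer donor-map loci onto a reference map
#'
#' Loci mapped only in a donor species are placed on the reference
#' (composite) map using shared anchor genes: a transferred locus is put at
#' the midpoint of the cM interval between the reference positions of its
#' two closest flanking anchors on the donor map. Donor loci outside the
#' anchor span are skipped with a warning (interior placement only; no
#' extrapolation). Anchors whose reference order is inverted relative to the
#' donor order raise an error for that chromosome.
#'
#' @param reference a \code{\link{genetic_map}}; its loci are untouched.
#' @param donor a \code{\link{genetic_map}} carrying loci to transfer.
#' @param anchors character vector of gene ids mapped on both maps.
#' @param species_tag species label given to transferred loci.
#' @return a \code{genetic_map} containing all reference loci plus the
#'   transferred donor-only loci, with attribute \code{n_transferred}.
#' @export
transfer_donor_loci <- function(reference, donor, anchors,
                                species_tag = "donor") {
  stopifnot(inherits(reference, "genetic_map"), inherits(donor, "genetic_map"))
  ref <- reference$loci
  don <- donor$loci
  anchors <- intersect(anchors, intersect(ref$gene_id, don$gene_id))
  if (length(anchors) < 2L) stop("need at least 2 shared anchor genes")
  to_move <- don[!(don$gene_id %in% ref$gene_id), , drop = FALSE]

  placed <- list()
  n_skipped <- 0L
  for (chr in unique(to_move$chromosome)) {
    anc <- don[don$chromosome == chr & don$gene_id %in% anchors, , drop = FALSE]
    anc <- anc[order(anc$position_cM), , drop = FALSE]
    if (nrow(anc) < 2L) {
      n_skipped <- n_skipped + sum(to_move$chromosome == chr)
      warning("donor chromosome ", chr,
              " has fewer than 2 anchors; its loci were skipped")
      next
    }
    ref_pos <- vapply(anc$gene_id, function(g)
      ref$position_cM[match(g, ref$gene_id)], numeric(1))
    ref_chr <- vapply(anc$gene_id, function(g)
      ref$chromosome[match(g, ref$gene_id)], character(1))
    if (length(unique(ref_chr)) != 1L)
      stop("anchors of donor chromosome ", chr,
           " map to several reference chromosomes")
    if (is.unsorted(ref_pos, strictly = FALSE))
      stop("anchor order conflict between donor and reference on donor chromosome ",
           chr)
    cand <- to_move[to_move$chromosome == chr, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      p <- cand$position_cM[i]
      on_anchor <- which(abs(anc$position_cM - p) < 1e-9)
      if (length(on_anchor)) {
        # degenerate interval: locus co-segregates with an anchor
        new_pos <- ref_pos[on_anchor[1]]
      } else if (p < min(anc$position_cM) || p > max(anc$position_cM)) {
        n_skipped <- n_skipped + 1L
        warning("donor locus ", cand$locus_id[i],
                " lies outside the anchor span; skipped")
        next
      } else {
        lo <- max(which(anc$position_cM < p))
        hi <- min(which(anc$position_cM > p))
        new_pos <- (ref_pos[lo] + ref_pos[hi]) / 2
      }
      row <- cand[i, , drop = FALSE]
      row$chromosome <- ref_chr[1]
      row$position_cM <- new_pos
      row$species <- species_tag
      placed[[length(placed) + 1L]] <- row
    }
  }
  new_loci <- if (length(placed)) rbind(ref, do.call(rbind, placed)) else ref
  out <- genetic_map(new_loci, reference$lengths)
  attr(out, "n_transferred") <- length(placed)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Groups of co-localizing loci
#'
#' Finds maximal groups of two or more loci on the same chromosome whose
#' pairwise cM differences are all at most \code{epsilon}. With the default
#' \code{epsilon = 0} the groups are exactly the sets of loci printed at
#' identical positions (zero observed recombinants), and groups partition
#' the tied loci. Given a term table, each group is annotated as
#' \code{same_family}, \code{functionally_related} (all members share at
#' least one term) or \code{unrelated}.
#'
#' @param map a \code{\link{genetic_map}}.
#' @param epsilon maximum pairwise position difference (cM), >= 0.
#' @param terms optional term table: data.frame with columns \code{gene_id},
#'   \code{term}.
#' @return list of groups; each a list with \code{chromosome},
#'   \code{position} range, \code{locus_ids}, \code{gene_ids},
#'   \code{relation}.
#' @export
colocalized_groups <- function(map, epsilon = 0, terms = NULL) {
  stopifnot(inherits(map, "genetic_map"), epsilon >= 0)
  groups <- list()
  for (chr in map$chromosomes) {
    loc <- map$loci[map$loci$chromosome == chr, , drop = FALSE]
    if (nrow(loc) < 2L) next
    loc <- loc[order(loc$position_cM, loc$locus_id), , drop = FALSE]
    p <- loc$position_cM
    n <- length(p)
    # maximal windows with max - min <= epsilon
    j <- 1L
    for (i in seq_len(n)) {
      while (j < n && p[j + 1L] - p[i] <= epsilon) j <- j + 1L
      if (j - i + 1L < 2L) next
      extendable_left <- i > 1L && p[j] - p[i - 1L] <= epsilon
      if (extendable_left) next  # contained in an earlier window
      groups[[length(groups) + 1L]] <- list(
        chromosome = chr,
        start = p[i], end = p[j],
        locus_ids = loc$locus_id[i:j],
        gene_ids = loc$gene_id[i:j],
        family_ids = loc$family_id[i:j])
    }
  }
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    fam <- g$family_ids[!is.na(g$family_ids)]
    relation <- if (length(fam) == length(g$family_ids) &&
                    length(unique(fam)) == 1L) {
      "same_family"
    } else if (!is.null(terms)) {
      shared <- Reduce(intersect, lapply(g$gene_ids, function(gi)
        terms$term[terms$gene_id == gi]))
      if (length(shared)) "functionally_related" else "unrelated"
    } else "unrelated"
    groups[[k]]$relation <- relation
  }
  groups
}

#' Co-expression verdicts for a group of genes
#'
#' Tests every gene pair in a co-localization group for correlated
#' expression across tissues (Pearson). The default reading of
#' co-regulation is one-sided positive correlation; set
#' \code{alternative = "two.sided"} for the symmetric test. A gene whose
#' expression has zero variance across tissues yields an undefined
#' correlation and the pair is reported not testable.
#'
#' @param genes character vector of gene ids (>= 2).
#' @param expr expression matrix, genes in rows (rownames are gene ids),
#'   tissues in columns; >= 3 tissues required.
#' @param alpha significance level for flagging, 0.01 or 0.05.
#' @param alternative "greater" (default, positive co-regulation) or
#'   "two.sided".
#' @return data.frame with one row per pair: \code{gene_a}, \code{gene_b},
#'   \code{r}, \code{p}, \code{coregulated}, \code{testable}; attribute
#'   \code{group_coregulated} is TRUE when all testable pairs are flagged
#'   and none is untestable.
#' @export
coexpression_flag <- function(genes, expr, alpha = 0.01,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(genes) >= 2L, alpha %in% c(0.01, 0.05))
  if (ncol(expr) < 3L) stop("need >= 3 tissues for correlation testing")
  missing_g <- setdiff(genes, rownames(expr))
  if (length(missing_g))
    stop("genes absent from expression matrix: ",
         paste(missing_g, collapse = ", "))
  pairs <- utils::combn(genes, 2L)
  res <- data.frame(gene_a = pairs[1, ], gene_b = pairs[2, ],
                    r = NA_real_, p = NA_real_,
                    coregulated = FALSE, testable = TRUE)
  for (i in seq_len(ncol(pairs))) {
    a <- as.numeric(expr[pairs[1, i], ])
    b <- as.numeric(expr[pairs[2, i], ])
    if (anyNA(a) || anyNA(b)) stop("missing expression values in tested pair")
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      res$testable[i] <- FALSE
      next
    }
    ct <- stats::cor.test(a, b, method = "pearson",
                          alternative = alternative)
    res$r[i] <- unname(ct$estimate)
    res$p[i] <- ct$p.value
    res$coregulated[i] <- ct$p.value < alpha
  }
  attr(res, "group_coregulated") <-
    all(res$testable) && all(res$coregulated)
  res
}

#' Term over-representation in a gene set
#'
#' Fisher exact test of each annotation term's frequency in a foreground
#' gene set against the remaining background, with Benjamini-Hochberg FDR.
#' Terms annotated to no gene in the universe are excluded.
#'
#' @param foreground character vector of gene ids; must be a subset of
#'   \code{background}.
#' @param background character vector of gene ids (the annotation universe).
#' @param terms data.frame with columns \code{gene_id}, \code{term}.
#' @param alpha FDR threshold used to set the \code{significant} flag.
#' @return data.frame, one row per term: counts of the 2x2 table,
#'   \code{odds_ratio}, \code{p}, \code{fdr}, \code{significant}, ordered by
#'   p-value.
#' @export
term_enrichment <- function(foreground, background, terms, alpha = 0.05) {
  if (length(foreground) == 0L) stop("empty foreground set")
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  foreground <- unique(foreground)
  background <- unique(background)
  rest <- setdiff(background, foreground)
  terms <- terms[terms$gene_id %in% background, , drop = FALSE]
  vocab <- sort(unique(terms$term))
  if (!length(vocab))
    return(data.frame(term = character(), fg_with = integer(),
                      fg_without = integer(), bg_with = integer(),
                      bg_without = integer(), odds_ratio = numeric(),
                      p = numeric(), fdr = numeric(),
                      significant = logical()))
  rows <- lapply(vocab, function(tm) {
    with_term <- unique(terms$gene_id[terms$term == tm])
    a <- sum(foreground %in% with_term)
    b <- length(foreground) - a
    c_ <- sum(rest %in% with_term)
    d <- length(rest) - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE))
    data.frame(term = tm, fg_with = a, fg_without = b,
               bg_with = c_, bg_without = d,
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr <= alpha
  out[order(out$p, out$term), , drop = FALSE]
}
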