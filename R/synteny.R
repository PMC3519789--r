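#' Read a BLAST tabular hit file (outfmt-6 subset)
#'
#' Expects at least columns qseqid, sseqid, pident, bitscore; a header
#' line is optional (detected when the third field is non-numeric).
#'
#' @param path TSV file.
#' @return data.frame with columns \code{qseqid}, \code{sseqid},
#'   \code{pident}, \code{bitscore}.
#' @export
read_hit_table <- function(path) {
  first <- readLines(path, n = 1L)
  f3 <- strsplit(first, "\t", fixed = TRUE)[[1]][3]
  has_header <- is.na(suppressWarnings(as.numeric(f3)))
  df <- utils::read.delim(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!has_header) names(df)[1:4] <- c("qseqid", "sseqid", "pident",
                                       "bitscore")
  need <- c("qseqid", "sseqid", "pident", "bitscore")
  if (!all(need %in% names(df)))
    stop("hit table must carry columns ", paste(need, collapse = ", "))
  df$pident <- as.numeric(df$pident)
  df$bitscore <- as.numeric(df$bitscore)
  if (any(df$pident < 0 | df$pident > 100)) stop("pident outside [0, 100]")
  df[, need]
}

.best_hit <- function(hits) {
  # deterministic best hit per query: score, then identity, then subject id
  hits <- hits[order(hits$qseqid, -hits$bitscore, -hits$pident,
                     hits$sseqid), , drop = FALSE]
  hits[!duplicated(hits$qseqid), , drop = FALSE]
}

#' Reciprocal best hits between two gene sets
#'
#' A pair (a, b) is retained when b is a's best hit in the a-vs-b table
#' and a is b's best hit in the b-vs-a table, both at or above
#' \code{min_identity} percent. Best hits are ordered by bitscore, ties
#' broken by identity then subject id, so the result is deterministic and
#' one-to-one.
#'
#' @param ab hits of A queries against B (data.frame as from
#'   \code{\link{read_hit_table}}).
#' @param ba hits of B queries against A.
#' @param min_identity percent identity threshold (default 80).
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{pident} (minimum of the two directions).
#' @export
reciprocal_best_hits <- function(ab, ba, min_identity = 80) {
  ab <- ab[ab$pident >= min_identity, , drop = FALSE]
  ba <- ba[ba$pident >= min_identity, , drop = FALSE]
  if (!nrow(ab) || !nrow(ba))
    return(data.frame(gene_a = character(), gene_b = character(),
                      pident = numeric()))
  best_ab <- .best_hit(ab)
  best_ba <- .best_hit(ba)
  m <- match(best_ab$sseqid, best_ba$qseqid)
  ok <- !is.na(m) & best_ba$sseqid[m] == best_ab$qseqid
  out <- data.frame(gene_a = best_ab$qseqid[ok],
                    gene_b = best_ab$sseqid[ok],
                    pident = pmin(best_ab$pident[ok],
                                  best_ba$pident[m][ok]))
  out[order(out$gene_a), , drop = FALSE]
}

#' Synteny assignment for cross-map homologous pairs
#'
#' Homoeologous chromosome pairing is determined by plurality: each
#' chromosome of map A is paired with the chromosome of map B receiving
#' most of its links (ties broken by the chromosome's total link count,
#' then label order). A link is syntenic iff it connects a homoeologous
#' chromosome pair. Duplicate links between the same two genes are
#' collapsed to one.
#'
#' @param map_a,map_b \code{\link{genetic_map}} objects.
#' @param pairs data.frame with columns \code{gene_a}, \code{gene_b} (as
#'   from \code{\link{reciprocal_best_hits}}).
#' @return object of class \code{synteny_links}: list with \code{links}
#'   (data.frame: gene_a, gene_b, chr_a, pos_a, chr_b, pos_b, syntenic),
#'   \code{homoeology} (data.frame chr_a -> chr_b with link counts),
#'   \code{pct_syntenic} (NA when there are no links).
#' @export
synteny_links <- function(map_a, map_b, pairs) {
  stopifnot(inherits(map_a, "genetic_map"), inherits(map_b, "genetic_map"))
  pairs <- pairs[!duplicated(pairs[, c("gene_a", "gene_b")]), , drop = FALSE]
  la <- map_a$loci[match(pairs$gene_a, map_a$loci$gene_id), ]
  lb <- map_b$loci[match(pairs$gene_b, map_b$loci$gene_id), ]
  keep <- !is.na(la$locus_id) & !is.na(lb$locus_id)
  if (!all(keep)) stop("pair genes absent from their maps")
  links <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                      chr_a = la$chromosome, pos_a = la$position_cM,
                      chr_b = lb$chromosome, pos_b = lb$position_cM)
  if (!nrow(links)) {
    out <- list(links = cbind(links, syntenic = logical(0)),
                homoeology = data.frame(chr_a = character(),
                                        chr_b = character(),
                                        n_links = integer()),
                pct_syntenic = NA_real_)
    class(out) <- "synteny_links"
    return(out)
  }
  homo <- lapply(unique(links$chr_a), function(ca) {
    sub <- links[links$chr_a == ca, , drop = FALSE]
    tab <- sort(table(sub$chr_b), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    data.frame(chr_a = ca, chr_b = sort(top)[1],
               n_links = nrow(sub))
  })
  homo <- do.call(rbind, homo)
  homo <- homo[order(homo$chr_a), , drop = FALSE]
  key <- paste(homo$chr_a, homo$chr_b)
  links$syntenic <- paste(links$chr_a, links$chr_b) %in% key
  structure(list(links = links, homoeology = homo,
                 pct_syntenic = 100 * mean(links$syntenic)),
            class = "synteny_links")
}

#' @export
print.synteny_links <- function(x, ...) {
  cat(sprintf("%d cross-map links; %s syntenic\n", nrow(x$links),
              if (is.na(x$pct_syntenic)) "NA"
              else sprintf("%d (%.1f%%)", sum(x$links$syntenic),
                           x$pct_syntenic)))
  invisible(x)
}

# longest nondecreasing subsequence (indices), O(n^2) DP; ties compatible
.lis_indices <- function(y) {
  n <- length(y)
  if (!n) return(integer(0))
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L))
    if (y[j] <= y[i] && len[j] + 1L > len[i]) {
      len[i] <- len[j] + 1L; prev[i] <- j
    }
  i <- which.max(len)
  out <- integer(0)
  while (i) { out <- c(i, out); i <- prev[i] }
  out
}

#' Collinear subset of syntenic links on one chromosome pair
#'
#' Links are sorted by map-A position; the collinear subset is a longest
#' nondecreasing subsequence of map-B positions (ties in either
#' coordinate compatible, so co-segregating loci never break
#' collinearity). With \code{orientation_aware = TRUE} the better of the
#' forward and reverse (nonincreasing) orientations is taken, so a whole
#' inverted chromosome still scores as collinear.
#'
#' @param links data.frame with columns \code{pos_a}, \code{pos_b} (one
#'   homoeologous chromosome pair).
#' @param orientation_aware accept the reverse orientation when better.
#' @return list with \code{collinear} (logical per link),
#'   \code{pct_collinear}, \code{orientation} ("forward"/"reverse").
#' @export
collinearity <- function(links, orientation_aware = TRUE) {
  n <- nrow(links)
  if (!n) return(list(collinear = logical(0), pct_collinear = NA_real_,
                      orientation = "forward"))
  ord <- order(links$pos_a, links$pos_b)
  y <- links$pos_b[ord]
  fwd <- .lis_indices(y)
  idx <- fwd; orientation <- "forward"
  if (orientation_aware) {
    rev_ <- .lis_indices(-y)
    if (length(rev_) > length(fwd)) { idx <- rev_; orientation <- "reverse" }
  }
  collinear <- logical(n)
  collinear[ord[idx]] <- TRUE
  list(collinear = collinear, pct_collinear = 100 * length(idx) / n,
       orientation = orientation)
}

#' Conserved segments and map coverage from collinear links
#'
#' Within each homoeologous chromosome pair, collinear links sorted along
#' map A are split into maximal runs whose consecutive inter-link gaps are
#' at most \code{max_gap} cM on both maps. Every run is a conserved
#' segment (a single isolated link forms a degenerate zero-span segment).
#' Coverage per map is the summed segment span divided by the total map
#' length.
#'
#' @param links data.frame of collinear links (columns \code{chr_a},
#'   \code{pos_a}, \code{chr_b}, \code{pos_b}).
#' @param map_a,map_b the two \code{\link{genetic_map}}s (for total
#'   lengths).
#' @param max_gap maximum within-segment gap in cM (default 20).
#' @return object of class \code{conserved_segments}: list with
#'   \code{segments} (data.frame: chr_a, chr_b, start_a, end_a, start_b,
#'   end_b, n_links), \code{coverage_a}, \code{coverage_b} (percent of
#'   map length).
#' @export
conserved_segments <- function(links, map_a, map_b, max_gap = 20) {
  segs <- list()
  if (nrow(links)) {
    for (key in unique(paste(links$chr_a, links$chr_b, sep = "\r"))) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      sub <- links[links$chr_a == parts[1] & links$chr_b == parts[2], ,
                   drop = FALSE]
      sub <- sub[order(sub$pos_a), , drop = FALSE]
      brk <- c(1, which(diff(sub$pos_a) > max_gap |
                          abs(diff(sub$pos_b)) > max_gap) + 1)
      run_id <- rep(seq_along(brk), diff(c(brk, nrow(sub) + 1)))
      for (rid in unique(run_id)) {
        r <- sub[run_id == rid, , drop = FALSE]
        segs[[length(segs) + 1L]] <- data.frame(
          chr_a = parts[1], chr_b = parts[2],
          start_a = min(r$pos_a), end_a = max(r$pos_a),
          start_b = min(r$pos_b), end_b = max(r$pos_b),
          n_links = nrow(r))
      }
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chr_a = character(), chr_b = character(),
               start_a = numeric(), end_a = numeric(),
               start_b = numeric(), end_b = numeric(),
               n_links = integer())
  structure(list(
    segments = segments,
    coverage_a = 100 * sum(segments$end_a - segments$start_a) /
      sum(map_a$lengths),
    coverage_b = 100 * sum(segments$end_b - segments$start_b) /
      sum(map_b$lengths),
    max_gap = max_gap), class = "conserved_segments")
}

#' @export
print.conserved_segments <- function(x, ...) {
  cat(sprintf(
    "%d conserved segments (gap cap %.0f cM); coverage %.1f%% (map A), %.1f%% (map B)\n",
    nrow(x$segments), x$max_gap, x$coverage_a, x$coverage_b))
  invisible(x)
}

#' Full two-map synteny analysis
#'
#' Chains reciprocal best hits, synteny assignment, per-chromosome-pair
#' collinearity and conserved-segment coverage.
#'
#' @param map_a,map_b \code{\link{genetic_map}}s.
#' @param ab,ba hit tables (both directions).
#' @param min_identity RBH identity threshold (percent).
#' @param max_gap conserved-segment gap cap (cM).
#' @param orientation_aware see \code{\link{collinearity}}.
#' @return object of class \code{synteny_analysis}: list with
#'   \code{rbh}, \code{synteny} (a \code{synteny_links}), \code{links}
#'   (with \code{collinear} flags), \code{pct_syntenic},
#'   \code{pct_collinear} (of syntenic links), \code{segments}.
#' @export
synteny_analysis <- function(map_a, map_b, ab, ba, min_identity = 80,
                             max_gap = 20, orientation_aware = TRUE) {
  rbh <- reciprocal_best_hits(ab, ba, min_identity)
  syn <- synteny_links(map_a, map_b, rbh)
  links <- syn$links
  links$collinear <- FALSE
  if (nrow(links)) {
    for (key in unique(paste(links$chr_a, links$chr_b, sep = "\r"))) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      sel <- which(links$chr_a == parts[1] & links$chr_b == parts[2] &
                     links$syntenic)
      if (!length(sel)) next
      cl <- collinearity(links[sel, , drop = FALSE], orientation_aware)
      links$collinear[sel] <- cl$collinear
    }
  }
  n_syn <- sum(links$syntenic)
  segs <- conserved_segments(links[links$collinear, , drop = FALSE],
                             map_a, map_b, max_gap)
  structure(list(rbh = rbh, synteny = syn, links = links,
                 pct_syntenic = syn$pct_syntenic,
                 pct_collinear = if (n_syn) 100 * sum(links$collinear) / n_syn
                                 else NA_real_,
                 segments = segs),
            class = "synteny_analysis")
}

#' @export
print.synteny_analysis <- function(x, ...) {
  cat(sprintf("Two-map synteny: %d RBH pairs, %d mapped links\n",
              nrow(x$rbh), nrow(x$links)))
  cat(sprintf("  %.1f%% syntenic; %.1f%% of syntenic links collinear\n",
              x$pct_syntenic, x$pct_collinear))
  print(x$segments)
  invisible(x)
}
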