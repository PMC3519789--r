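#' Detect tandemly arrayed genes
#'
#' Within each family and chromosome, loci are chained by single linkage:
#' consecutive members (in map order) at most \code{w_outer} cM apart
#' belong to one chain. Chains of two or more loci are tandem arrays
#' (TAGs). An array is classed \code{"1cM"} when every consecutive gap is
#' at most \code{w_inner}, \code{"5cM"} otherwise.
#'
#' @param map a \code{\link{genetic_map}}; only loci with a family id are
#'   considered.
#' @param w_inner inner window (cM), default 1.
#' @param w_outer outer window (cM), default 5.
#' @return object of class \code{tag_arrays}: data.frame with one row per
#'   array: \code{family_id}, \code{chromosome}, \code{n_members},
#'   \code{start}, \code{end}, \code{span}, \code{window_class},
#'   \code{members} (comma-joined locus ids).
#' @export
detect_tags <- function(map, w_inner = 1, w_outer = 5) {
  stopifnot(inherits(map, "genetic_map"), w_inner <= w_outer)
  loc <- map$loci[!is.na(map$loci$family_id), , drop = FALSE]
  rows <- list()
  for (key in unique(paste(loc$family_id, loc$chromosome, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- loc[loc$family_id == parts[1] & loc$chromosome == parts[2], ,
               drop = FALSE]
    if (nrow(sub) < 2L) next
    sub <- sub[order(sub$position_cM, sub$locus_id), , drop = FALSE]
    gaps <- diff(sub$position_cM)
    chain_id <- cumsum(c(1, gaps > w_outer))
    for (cid in unique(chain_id)) {
      idx <- which(chain_id == cid)
      if (length(idx) < 2L) next
      g <- gaps[idx[-length(idx)]]
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = parts[1], chromosome = parts[2],
        n_members = length(idx),
        start = sub$position_cM[idx[1]],
        end = sub$position_cM[idx[length(idx)]],
        span = sub$position_cM[idx[length(idx)]] - sub$position_cM[idx[1]],
        window_class = if (all(g <= w_inner)) "1cM" else "5cM",
        members = paste(sub$locus_id[idx], collapse = ","))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family_id = character(), chromosome = character(),
               n_members = integer(), start = numeric(), end = numeric(),
               span = numeric(), window_class = character(),
               members = character())
  out <- out[order(out$family_id, out$chromosome, out$start), , drop = FALSE]
  class(out) <- c("tag_arrays", "data.frame")
  out
}

#' @export
print.tag_arrays <- function(x, ...) {
  cat(sprintf("%d tandem arrays (%d within 1 cM, %d within 5 cM), %d loci\n",
              nrow(x), sum(x$window_class == "1cM"),
              sum(x$window_class == "5cM"), sum(x$n_members)))
  if (nrow(x)) print(as.data.frame(x)[, setdiff(names(x), "members")],
                     row.names = FALSE)
  invisible(x)
}

#' Pearson chi-square against equal expected frequencies
#'
#' For k observed category counts, tests the null that all categories are
#' equally likely (expected = total/k each).
#'
#' @param counts non-negative integer counts, length >= 2, total > 0.
#' @return the chi-square statistic.
#' @export
equal_expected_chisq <- function(counts) {
  stopifnot(length(counts) >= 2L, all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("all counts are zero")
  expected <- total / length(counts)
  sum((counts - expected)^2 / expected)
}

#' Permutation test of gene-family dispersion over chromosomes
#'
#' Observed statistic: for each family, the number of distinct chromosomes
#' its mapped members occupy; families are then tallied into categories
#' k = 1..C. The null redistributes family labels at random over the fixed
#' set of mapped positions, preserving family sizes and the per-chromosome
#' locus counts, and re-tallies; expected category counts are the means
#' over \code{R} replicates. Categories with expected count below 1 are
#' pooled upward (into the next lower k with expectation >= 1) before the
#' chi-square is formed. Each family also receives an empirical p-value:
#' the fraction of replicates in which its randomized chromosome count is
#' at most its observed count (small when the family is more concentrated
#' than chance predicts); families at p <= 0.05 are flagged.
#'
#' @param map a \code{\link{genetic_map}} whose loci carry family ids.
#' @param R number of replicates (>= 100).
#' @param seed RNG seed (required for reproducibility).
#' @param members optional character vector of locus ids restricting the
#'   redistributed member set.
#' @return object of class \code{dispersion_test}: list with
#'   \code{observed} (per-category family counts), \code{expected},
#'   \code{chi_square}, \code{df} (= C - 1), \code{families} (per-family
#'   data.frame with \code{family_id}, \code{n_members},
#'   \code{n_chromosomes}, \code{p}, \code{flagged}), \code{R}.
#' @export
permute_family_dispersion <- function(map, R = 1000, seed, members = NULL) {
  stopifnot(inherits(map, "genetic_map"), R >= 100)
  if (missing(seed)) stop("a seed is required")
  loc <- map$loci[!is.na(map$loci$family_id), , drop = FALSE]
  if (!is.null(members)) loc <- loc[loc$locus_id %in% members, , drop = FALSE]
  if (!nrow(loc)) stop("no family-labelled loci")
  C <- length(map$chromosomes)
  fam <- loc$family_id
  fam_f <- factor(fam, levels = sort(unique(fam)))
  fam_levels <- levels(fam_f)
  n_fam <- length(fam_levels)
  n_mem <- nrow(loc)
  # the null redistributes family members over the positions of ALL
  # mapped loci, so chromosome occupancy probabilities follow the
  # realized per-chromosome locus counts
  pool_chr <- map$loci$chromosome

  count_per_family <- function(chrs)
    vapply(split(chrs, fam_f), function(z) length(unique(z)), integer(1))

  obs_counts <- count_per_family(loc$chromosome)
  obs_cat <- tabulate(obs_counts, nbins = C)

  set.seed(seed)
  sim_cat <- matrix(0L, nrow = R, ncol = C)
  le_obs <- integer(n_fam)  # replicates with simulated count <= observed
  for (r in seq_len(R)) {
    cnt <- count_per_family(pool_chr[sample.int(length(pool_chr), n_mem)])
    sim_cat[r, ] <- tabulate(cnt, nbins = C)
    le_obs <- le_obs + as.integer(cnt <= obs_counts)
  }
  expected <- colMeans(sim_cat)

  # pool categories with expected < 1 into the nearest lower category
  pool <- seq_len(C)
  if (C > 1L)
    for (k in C:2) if (expected[k] < 1) pool[pool == k] <- k - 1L
  obs_p <- tapply(obs_cat, pool, sum)
  exp_p <- tapply(expected, pool, sum)
  keep <- exp_p > 0
  chi <- sum((obs_p[keep] - exp_p[keep])^2 / exp_p[keep])

  families <- data.frame(
    family_id = fam_levels,
    n_members = as.integer(table(factor(fam, levels = fam_levels))),
    n_chromosomes = as.integer(obs_counts),
    p = le_obs / R)
  families$flagged <- families$p <= 0.05 & families$n_members >= 2L

  structure(list(observed = obs_cat, expected = expected,
                 chi_square = chi, df = C - 1L,
                 families = families, R = R),
            class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat(sprintf(
    "Family dispersion permutation test (R = %d): chi-square = %.1f, df = %d\n",
    x$R, x$chi_square, x$df))
  cat(sprintf("%d of %d families flagged as single-/few-chromosome concentrated (p <= 0.05)\n",
              sum(x$families$flagged), nrow(x$families)))
  invisible(x)
}

#' Translocation and distance statistics for classified gene pairs
#'
#' For gene pairs labelled by duplication age (ancient = predating the
#' gymnosperm-angiosperm split, recent = postdating it) with both members
#' mapped, tallies same-chromosome vs translocated pairs per age class,
#' tests each split against a 50:50 expectation
#' (\code{\link{equal_expected_chisq}}), computes same-chromosome cM
#' distances and their class means, and compares the two distance sets
#' with a Welch two-sample t-test (unequal variances,
#' Welch-Satterthwaite df).
#'
#' @param pairs data.frame with columns \code{label} (\code{"ancient"} or
#'   \code{"recent"}; other labels ignored), \code{chr_a}, \code{pos_a},
#'   \code{chr_b}, \code{pos_b}.
#' @return object of class \code{translocation_stats}: list with
#'   \code{by_class} (data.frame: class, n, same_chromosome, translocated,
#'   chi_square, mean_distance), \code{t}, \code{df}, \code{p} (Welch test;
#'   NA when a class has fewer than 2 same-chromosome pairs), and
#'   \code{distances} (list of the two distance vectors).
#' @export
duplicate_distance_stats <- function(pairs) {
  stopifnot(all(c("label", "chr_a", "pos_a", "chr_b", "pos_b") %in%
                  names(pairs)))
  classes <- c("ancient", "recent")
  dist_sets <- list()
  rows <- lapply(classes, function(cl) {
    sub <- pairs[pairs$label == cl, , drop = FALSE]
    same <- sub$chr_a == sub$chr_b
    d <- abs(sub$pos_a - sub$pos_b)[same]
    dist_sets[[cl]] <<- d
    chi <- if (nrow(sub) > 0) equal_expected_chisq(c(sum(same), sum(!same)))
           else NA_real_
    data.frame(class = cl, n = nrow(sub),
               same_chromosome = sum(same), translocated = sum(!same),
               pct_translocated = if (nrow(sub)) 100 * sum(!same) / nrow(sub)
                                  else NA_real_,
               chi_square = chi,
               mean_distance = if (length(d)) mean(d) else NA_real_)
  })
  by_class <- do.call(rbind, rows)
  if (length(dist_sets$ancient) >= 2L && length(dist_sets$recent) >= 2L) {
    tt <- stats::t.test(dist_sets$recent, dist_sets$ancient,
                        var.equal = FALSE)
    t_stat <- unname(tt$statistic); t_df <- unname(tt$parameter)
    t_p <- tt$p.value
  } else {
    t_stat <- NA_real_; t_df <- NA_real_; t_p <- NA_real_
  }
  structure(list(by_class = by_class, t = t_stat, df = t_df, p = t_p,
                 distances = dist_sets),
            class = "translocation_stats")
}

#' @export
print.translocation_stats <- function(x, ...) {
  cat("Same-chromosome vs translocated duplicate pairs by age class:\n")
  df <- x$by_class
  df$chi_square <- round(df$chi_square, 1)
  df$mean_distance <- round(df$mean_distance, 1)
  df$pct_translocated <- round(df$pct_translocated, 1)
  print(df, row.names = FALSE)
  if (!is.na(x$t))
    cat(sprintf("Welch t (recent vs ancient distances): t = %.1f, df = %.1f, p = %.2g\n",
                x$t, x$df, x$p))
  invisible(x)
}
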