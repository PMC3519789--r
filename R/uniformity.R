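# Critical values for the modified KS statistic D*; the multiplier
# (sqrt(n) - 0.01 + 0.85/sqrt(n)) makes them independent of sample size.
.dstar_critical <- c("0.15" = 0.775, "0.10" = 0.819, "0.05" = 0.895,
                     "0.025" = 0.955, "0.01" = 1.035)

#' Kolmogorov-Smirnov statistic against a uniform distribution
#'
#' Computes D = sup_x |F_n(x) - x/L| for gene positions on a chromosome of
#' length L, evaluating the empirical CDF on both sides of each jump (the
#' supremum of the difference against a continuous null is attained at a
#' jump point). Ties contribute multiple CDF steps.
#'
#' @param positions numeric vector of cM positions, all within
#'   \code{[0, length]}.
#' @param length chromosome length in cM.
#' @return the statistic D in \code{[0, 1]}.
#' @export
ks_statistic <- function(positions, length) {
  n <- base::length(positions)
  if (n < 1L) stop("empty position vector")
  if (any(positions < 0 | positions > length))
    stop("positions outside [0, length]")
  u <- sort(positions) / length
  i <- seq_len(n)
  max(pmax(i / n - u, u - (i - 1) / n))
}

#' Modified KS statistic and its significance band
#'
#' Rescales D to D* = D (sqrt(n) - 0.01 + 0.85/sqrt(n)), whose critical
#' values do not depend on n (0.895 at alpha = 0.05, 1.035 at alpha = 0.01),
#' and reports the tightest significance band D* reaches in the critical
#' table. Exact finite-sample p-values are out of scope; the band is the
#' reported quantity.
#'
#' @param D KS statistic in \code{[0, 1]}.
#' @param n number of loci (>= 2).
#' @return list with \code{Dstar} and \code{p_class} (e.g. \code{"<=0.01"},
#'   \code{">0.15"}).
#' @export
modified_ks_test <- function(D, n) {
  stopifnot(n >= 2, D >= 0, D <= 1)
  Dstar <- D * (sqrt(n) - 0.01 + 0.85 / sqrt(n))
  crit <- .dstar_critical
  reached <- crit[Dstar >= crit]
  p_class <- if (base::length(reached))
    paste0("<=", names(reached)[base::length(reached)]) else ">0.15"
  list(Dstar = Dstar, p_class = p_class)
}

#' Per-chromosome test of uniform gene distribution
#'
#' Runs the KS uniformity test on every chromosome of a map, reporting the
#' raw statistic D, the sample-size-independent D* and the significance
#' band, one row per chromosome.
#'
#' @param map a \code{\link{genetic_map}}.
#' @return object of class \code{uniformity_test}: a data.frame with
#'   columns \code{chromosome}, \code{n}, \code{length_cM}, \code{D},
#'   \code{Dstar}, \code{p_class}.
#' @export
uniformity_test <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  rows <- lapply(map$chromosomes, function(chr) {
    pos <- map$loci$position_cM[map$loci$chromosome == chr]
    L <- map$lengths[[chr]]
    if (base::length(pos) < 2L)
      return(data.frame(chromosome = chr, n = base::length(pos),
                        length_cM = L, D = NA_real_, Dstar = NA_real_,
                        p_class = NA_character_))
    D <- ks_statistic(pos, L)
    m <- modified_ks_test(D, base::length(pos))
    data.frame(chromosome = chr, n = base::length(pos), length_cM = L,
               D = D, Dstar = m$Dstar, p_class = m$p_class)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("uniformity_test", "data.frame")
  out
}

#' @export
print.uniformity_test <- function(x, digits = 4, ...) {
  cat("Uniformity of gene distribution (modified KS test)\n")
  cat("Critical D*: 0.895 (alpha = 0.05), 1.035 (alpha = 0.01)\n\n")
  df <- as.data.frame(x)
  df$D <- round(df$D, digits)
  df$Dstar <- round(df$Dstar, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
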