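#' Generate the full set of pipeline inputs for a synthetic scenario
#'
#' Bundles the three generators: a structured map (density, tandem
#' arrays, dispersion), gene-family tree pairs with their own focal-gene
#' map (duplication dating, translocation statistics) and a homologous
#' map pair with hit tables (synteny). Ground truths are kept alongside.
#'
#' @param cfg a \code{\link{scenario_config}}.
#' @return list with \code{map}, \code{nj}, \code{mp}, \code{dating_map},
#'   \code{map_a}, \code{map_b}, \code{ab}, \code{ba}, \code{truth}
#'   (list: map, trees, pair).
#' @export
simulate_inputs <- function(cfg) {
  sm <- simulate_map(cfg)
  st <- simulate_family_trees(cfg)
  sp <- simulate_map_pair(cfg)
  list(map = sm$map, nj = st$nj, mp = st$mp, dating_map = st$map,
       map_a = sp$map_a, map_b = sp$map_b, ab = sp$ab, ba = sp$ba,
       truth = list(map = sm$truth, trees = st$truth, pair = sp$truth))
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order: uniformity testing,
#' gene-rich-region calling and tandem-array detection on the map;
#' family-dispersion permutation test; duplication dating from the tree
#' pairs; translocation/distance statistics on the dated pairs; two-map
#' synteny. A stage whose required inputs are absent raises an error
#' naming it.
#'
#' @param inputs list as produced by \code{\link{simulate_inputs}}, or
#'   assembled by hand: \code{map} (uniformity/grr/tags/dispersion),
#'   \code{nj}, \code{mp} and \code{dating_map} (dating, translocation),
#'   \code{map_a}, \code{map_b}, \code{ab}, \code{ba} (synteny).
#' @param stages character vector of stage names to run.
#' @param alpha significance level for density bands and GRR calls.
#' @param R dispersion-test replicates.
#' @param seed seed for the permutation test.
#' @param min_support support-collapse threshold (percent) for dating.
#' @param min_identity RBH identity threshold (percent).
#' @param max_gap conserved-segment gap cap (cM).
#' @param grid_step density grid spacing (cM).
#' @return object of class \code{macromap_report}: named list of stage
#'   results plus \code{settings}.
#' @export
run_pipeline <- function(inputs,
                         stages = c("uniformity", "grr", "tags",
                                    "dispersion", "dating",
                                    "translocation", "synteny"),
                         alpha = 0.05, R = 1000, seed = 1,
                         min_support = 50, min_identity = 80,
                         max_gap = 20, grid_step = 0.5) {
  need <- function(stage, fields) {
    miss <- fields[!vapply(fields, function(f)
      !is.null(inputs[[f]]), logical(1))]
    if (length(miss))
      stop("stage '", stage, "' is missing required inputs: ",
           paste(miss, collapse = ", "))
  }
  out <- list(settings = list(stages = stages, alpha = alpha, R = R,
                              seed = seed, min_support = min_support,
                              min_identity = min_identity,
                              max_gap = max_gap, grid_step = grid_step))
  if ("uniformity" %in% stages) {
    need("uniformity", "map")
    out$uniformity <- uniformity_test(inputs$map)
  }
  if ("grr" %in% stages) {
    need("grr", "map")
    out$grr <- map_grrs(inputs$map, alpha = alpha, grid_step = grid_step)
  }
  if ("tags" %in% stages) {
    need("tags", "map")
    out$tags <- detect_tags(inputs$map)
  }
  if ("dispersion" %in% stages) {
    need("dispersion", "map")
    out$dispersion <- permute_family_dispersion(inputs$map, R = R,
                                                seed = seed)
  }
  if ("dating" %in% stages) {
    need("dating", c("nj", "mp", "dating_map"))
    out$dating <- classify_families(inputs$nj, inputs$mp,
                                    inputs$dating_map,
                                    min_support = min_support)
  }
  if ("translocation" %in% stages) {
    if (is.null(out$dating))
      stop("stage 'translocation' requires the 'dating' stage output")
    out$translocation <- duplicate_distance_stats(out$dating$pairs)
  }
  if ("synteny" %in% stages) {
    need("synteny", c("map_a", "map_b", "ab", "ba"))
    out$synteny <- synteny_analysis(inputs$map_a, inputs$map_b,
                                    inputs$ab, inputs$ba,
                                    min_identity = min_identity,
                                    max_gap = max_gap)
  }
  class(out) <- "macromap_report"
  out
}

#' Write a consolidated pipeline report
#'
#' Serializes per-stage tables and the headline quantities
#' (ancient:recent ratio, percent syntenic/collinear) to a JSON file and
#' a human-readable text summary.
#'
#' @param report a \code{macromap_report}.
#' @param out_dir output directory (created if absent).
#' @return named vector of the files written, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "macromap_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  summary <- report_summary(report)
  json_path <- file.path(out_dir, "report.json")
  payload <- list(settings = report$settings, summary = summary)
  for (stage in c("uniformity", "grr", "tags")) {
    if (!is.null(report[[stage]]))
      payload[[stage]] <- as.data.frame(report[[stage]])
  }
  if (!is.null(report$dating))
    payload$dating <- list(tally = as.list(report$dating$tally),
                           percentages = as.list(report$dating$percentages))
  if (!is.null(report$translocation))
    payload$translocation <- list(
      by_class = report$translocation$by_class,
      welch_t = report$translocation$t,
      welch_df = report$translocation$df,
      welch_p = report$translocation$p)
  if (!is.null(report$synteny))
    payload$synteny <- list(pct_syntenic = report$synteny$pct_syntenic,
                            pct_collinear = report$synteny$pct_collinear,
                            segments = report$synteny$segments$segments)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  txt_path <- file.path(out_dir, "report.txt")
  con <- file(txt_path, "w")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  sink(); close(con); on.exit(NULL)
  invisible(c(json = json_path, text = txt_path))
}

#' Headline quantities of a pipeline report
#'
#' @param report a \code{macromap_report}.
#' @return named list of the main per-stage quantities.
#' @export
report_summary <- function(report) {
  s <- list()
  if (!is.null(report$uniformity))
    s$n_nonuniform_chromosomes_0.05 <-
      sum(report$uniformity$Dstar >= 0.895, na.rm = TRUE)
  if (!is.null(report$grr)) s$n_grr <- nrow(report$grr)
  if (!is.null(report$tags)) {
    s$n_tags <- nrow(report$tags)
    s$n_tags_1cM <- sum(report$tags$window_class == "1cM")
  }
  if (!is.null(report$dispersion)) {
    s$dispersion_chi_square <- report$dispersion$chi_square
    s$n_flagged_families <- sum(report$dispersion$families$flagged)
  }
  if (!is.null(report$dating)) {
    s <- c(s, as.list(report$dating$tally),
           as.list(report$dating$percentages))
  }
  if (!is.null(report$translocation)) {
    bc <- report$translocation$by_class
    s$pct_translocated_ancient <-
      bc$pct_translocated[bc$class == "ancient"]
    s$pct_translocated_recent <-
      bc$pct_translocated[bc$class == "recent"]
    s$mean_distance_ancient <- bc$mean_distance[bc$class == "ancient"]
    s$mean_distance_recent <- bc$mean_distance[bc$class == "recent"]
    s$welch_t <- report$translocation$t
  }
  if (!is.null(report$synteny)) {
    s$pct_syntenic <- report$synteny$pct_syntenic
    s$pct_collinear <- report$synteny$pct_collinear
  }
  s
}

#' @export
print.macromap_report <- function(x, ...) {
  cat("== macromap pipeline report ==\n")
  for (stage in c("uniformity", "grr", "tags", "dispersion", "dating",
                  "translocation", "synteny")) {
    if (is.null(x[[stage]])) next
    cat("\n--", stage, "--\n")
    print(x[[stage]])
  }
  invisible(x)
}
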