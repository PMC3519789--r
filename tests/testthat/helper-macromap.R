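# shared fixtures and independent oracles, built in code

toy_map <- function(positions, chromosome = "1", length = 100,
                    family = NA_character_) {
  n <- length(positions)
  genetic_map(
    data.frame(locus_id = paste0("L", seq_len(n)),
               gene_id = paste0("G", seq_len(n)),
               chromosome = chromosome, position_cM = positions,
               family_id = family, species = "focal"),
    stats::setNames(length, chromosome[1]))
}

random_map <- function(n = 50, lengths = c(`1` = 100, `2` = 80), seed = 1) {
  set.seed(seed)
  chr <- sample(names(lengths), n, replace = TRUE)
  genetic_map(
    data.frame(locus_id = sprintf("L%03d", seq_len(n)),
               gene_id = sprintf("G%03d", seq_len(n)),
               chromosome = chr,
               position_cM = runif(n, 0, lengths[chr]),
               family_id = sample(c(NA, "Fa", "Fb"), n, replace = TRUE),
               species = "focal"),
    lengths)
}

tree_of <- function(newick) as_support_tree(ape::read.tree(text = newick))

# independent bipartition enumeration via phangorn (oracle for consensus)
oracle_split_keys <- function(tree) {
  labs <- sort(tree$tip.label)
  n <- length(labs)
  m <- as.matrix(phangorn::as.splits(tree))
  keys <- character(0)
  for (r in seq_len(nrow(m))) {
    side <- match(colnames(m)[m[r, ] == 1], labs)
    if (1L %in% side) side <- setdiff(seq_len(n), side)
    side <- sort(side)
    if (length(side) >= 2L && length(side) <= n - 2L)
      keys <- c(keys, paste(side, collapse = ","))
  }
  unique(keys)
}

split_keys <- function(st)
  vapply(st$splits, function(s) paste(s, collapse = ","), character(1))

# exhaustive longest nondecreasing subsequence (oracle for collinearity)
brute_lis_length <- function(y) {
  n <- length(y)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) <= best) next
    if (all(diff(y[idx]) >= 0)) best <- length(idx)
  }
  best
}
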