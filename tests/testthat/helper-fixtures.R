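# Shared fixtures: the published Scottish 2022 aggregate tables, rebuilt in
# code, plus small record/matrix builders used across test files.

treatment_outcome_counts <- function() {
  m <- matrix(c(113, 0, 2, 2,
                37, 0, 15, 1,
                49, 51, 2, 6,
                56, 62, 1, 2),
              nrow = 4, byrow = TRUE,
              dimnames = list(treatment_levels(), outcome_levels()))
  m
}

stage_outcome_counts <- function() {
  matrix(c(26, 4, 1, 1,
           142, 79, 13, 10,
           87, 30, 6, 0),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("adult", "larva", "pupa"), outcome_levels()))
}

# one record per count, optionally spread round-robin over blocks so
# block-level analyses have data
counts_to_records <- function(counts, row_field, col_field,
                              n_blocks = NULL) {
  tab <- as_crosstab(counts, row_field, col_field)
  rec <- crosstab_to_records(tab)
  if (!is.null(n_blocks)) {
    rec$block <- rep_len(sprintf("B%02d", seq_len(n_blocks)), nrow(rec))
  }
  rec
}

random_crosstab <- function(nr, nc, lambda = 8) {
  repeat {
    m <- matrix(rpois(nr * nc, lambda), nr,
                dimnames = list(paste0("r", seq_len(nr)),
                                paste0("c", seq_len(nc))))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# brute-force chi-square: explicit double loop over cells
chisq_by_hand <- function(counts) {
  n <- sum(counts)
  stat <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      e <- sum(counts[i, ]) * sum(counts[, j]) / n
      stat <- stat + (counts[i, j] - e)^2 / e
    }
  }
  stat
}

small_community <- function(counts, treatment = NULL, block = NULL) {
  n <- nrow(counts)
  if (is.null(treatment)) treatment <- rep_len(c("control", "fungi"), n)
  if (is.null(block)) block <- rep_len(sprintf("B%02d", 1:2), n)
  community_matrix(counts, block = block, treatment = treatment)
}
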