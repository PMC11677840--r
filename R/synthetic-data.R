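#' Simulate destructive-sampling weevil records
#'
#' Generates one row per destructively sampled weevil: block, treatment,
#' developmental stage, infection outcome, depth (cm, negative below
#' ground) and longitudinal distance to the stump bole (cm, non-negative).
#' By default the trial layout is a complete randomised block design --
#' every block contains one stump per treatment -- and the number of
#' weevils found under each stump is Poisson with mean
#' `cfg$weevils_per_stump`. Stage is drawn from `stage_probs`, outcome from
#' the treatment's `outcome_probs`, depth from a per-outcome normal
#' location model (mostly below ground, with the small positive tail the
#' normal allows), and distance from a zero-inflated exponential (the
#' field medians sit at 0).
#'
#' @param cfg A [simulation_config()].
#' @param n_records Optional total record count. When given, block and
#'   treatment are drawn uniformly instead of using the per-stump Poisson
#'   layout; useful for large-sample frequency checks.
#' @return A data.frame with columns `block`, `treatment`, `stage`,
#'   `outcome`, `depth_cm`, `dist_bole_cm`. Reproducible for a fixed
#'   config seed (dataset substream 1).
#' @examples
#' rec <- simulate_destructive(simulation_config(seed = 42, n_blocks = 3))
#' table(rec$treatment, rec$outcome)
#' @export
simulate_destructive <- function(cfg, n_records = NULL) {
  validate_simulation_config(cfg)
  set.seed(substream_seed(cfg$seed, 1L))
  blocks <- sprintf("B%02d", seq_len(cfg$n_blocks))
  if (is.null(n_records)) {
    stumps <- expand.grid(block = blocks, treatment = cfg$treatments,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    per_stump <- stats::rpois(nrow(stumps), cfg$weevils_per_stump)
    block <- rep(stumps$block, per_stump)
    treatment <- rep(stumps$treatment, per_stump)
  } else {
    block <- sample(blocks, n_records, replace = TRUE)
    treatment <- sample(cfg$treatments, n_records, replace = TRUE)
  }
  n <- length(block)
  stage <- sample(names(cfg$stage_probs), n, replace = TRUE,
                  prob = cfg$stage_probs)
  outcome <- character(n)
  for (tr in cfg$treatments) {
    idx <- which(treatment == tr)
    if (length(idx) > 0) {
      outcome[idx] <- sample(names(cfg$outcome_probs[[tr]]), length(idx),
                             replace = TRUE, prob = cfg$outcome_probs[[tr]])
    }
  }
  depth <- numeric(n)
  dist <- numeric(n)
  for (oc in outcome_levels()) {
    idx <- which(outcome == oc)
    if (length(idx) == 0) next
    dm <- cfg$depth_model[[oc]]
    depth[idx] <- stats::rnorm(length(idx), dm$mean, dm$sd)
    xm <- cfg$distance_model[[oc]]
    zero <- stats::runif(length(idx)) < xm$p_zero
    cond_mean <- xm$mean / max(1 - xm$p_zero, 1e-12)
    d <- stats::rexp(length(idx), rate = 1 / cond_mean)
    d[zero] <- 0
    dist[idx] <- d
  }
  data.frame(block = block, treatment = treatment, stage = stage,
             outcome = outcome, depth_cm = depth, dist_bole_cm = dist,
             stringsAsFactors = FALSE)
}

#' Simulate per-stump emergence counts
#'
#' One record per (block, treatment) stump-trap: the number of adult
#' weevils caught over a season. Counts follow an NB2 negative binomial,
#' `count ~ NB(mu, theta)` with `Var = mu + mu^2/theta`, where
#' `mu = exp(intercept + b_block + log(rate_ratio[treatment]))` and block
#' effects `b_block ~ Normal(0, block_sd^2)` are shared across the
#' treatments within a block (the randomised-block structure).
#'
#' @param cfg A [simulation_config()].
#' @return A data.frame with columns `block`, `treatment`, `emerged`,
#'   forming a complete block-by-treatment layout (dataset substream 2).
#' @examples
#' em <- simulate_emergence(simulation_config(seed = 7, n_blocks = 10))
#' aggregate(emerged ~ treatment, em, mean)
#' @export
simulate_emergence <- function(cfg) {
  validate_simulation_config(cfg)
  set.seed(substream_seed(cfg$seed, 2L))
  blocks <- sprintf("B%02d", seq_len(cfg$n_blocks))
  b_eff <- stats::rnorm(cfg$n_blocks, 0, cfg$block_sd)
  grid <- expand.grid(block = blocks, treatment = cfg$treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- exp(cfg$emergence_intercept + b_eff[match(grid$block, blocks)] +
              log(cfg$rate_ratios[grid$treatment]))
  grid$emerged <- stats::rnbinom(nrow(grid), mu = mu,
                                 size = cfg$nb_dispersion)
  grid[order(grid$block, match(grid$treatment, cfg$treatments)), ,
       drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Simulate a trap-by-taxon community matrix
#'
#' One pitfall/emergence trap per (block, treatment); counts for each taxon
#' are independent Poisson draws with expectation
#' `community_taxon_means[taxon] * community_effect[treatment]`. With all
#' effects at 1 this is the null community in which treatment carries no
#' compositional signal.
#'
#' @param cfg A [simulation_config()].
#' @param granularity Label recorded on the matrix, `"broad"` (orders) or
#'   `"narrow"` (families/species); the generator itself is agnostic.
#' @return A [community_matrix()] (dataset substream 3).
#' @export
simulate_community <- function(cfg, granularity = c("broad", "narrow")) {
  validate_simulation_config(cfg)
  granularity <- match.arg(granularity)
  set.seed(substream_seed(cfg$seed, 3L))
  blocks <- sprintf("B%02d", seq_len(cfg$n_blocks))
  grid <- expand.grid(block = blocks, treatment = cfg$treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  taxa <- names(cfg$community_taxon_means)
  lambda <- outer(cfg$community_effect[grid$treatment],
                  cfg$community_taxon_means)
  counts <- matrix(stats::rpois(length(lambda), lambda),
                   nrow = nrow(grid), dimnames = list(NULL, taxa))
  community_matrix(counts,
                   block = grid$block, treatment = grid$treatment,
                   traps = paste(grid$block, grid$treatment, sep = "_"),
                   granularity = granularity)
}

#' Write the three synthetic datasets as CSV
#'
#' Emits `destructive.csv` (block, treatment, stage, outcome, depth_cm,
#' dist_bole_cm), `emergence.csv` (block, treatment, emerged) and
#' `community.csv` (trap, block, treatment, one column per taxon) under
#' `dir`.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulated_datasets <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(destructive = file.path(dir, "destructive.csv"),
             emergence = file.path(dir, "emergence.csv"),
             community = file.path(dir, "community.csv"))
  utils::write.csv(simulate_destructive(cfg), paths[["destructive"]],
                   row.names = FALSE)
  utils::write.csv(simulate_emergence(cfg), paths[["emergence"]],
                   row.names = FALSE)
  cm <- simulate_community(cfg)
  utils::write.csv(as.data.frame(cm), paths[["community"]],
                   row.names = FALSE)
  invisible(paths)
}
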