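#' Simulation configuration for a randomised-block biocontrol trial
#'
#' Builds the parameter set that drives all three synthetic datasets:
#' record-level destructive-sampling data (one row per weevil), per-stump
#' emergence counts, and trap-by-taxon community matrices. Defaults come
#' from a versioned JSON document shipped with the package
#' (`sim-defaults.json`) whose outcome, stage and emergence-ratio values
#' emulate the Scottish 2022 field trial; any field can be overridden.
#'
#' @param ... Named overrides of default fields. Recognised fields:
#'   `seed` (integer root seed; per-dataset substreams are derived from it),
#'   `n_blocks`, `treatments` (character, control first), `outcome_probs`
#'   (named list, one probability vector over
#'   alive/nematode_killed/fungus_killed/indeterminate per treatment),
#'   `stage_probs` (probabilities over larva/pupa/adult),
#'   `weevils_per_stump` (Poisson mean of weevils found per stump),
#'   `emergence_intercept` (log-scale control mean emergence),
#'   `rate_ratios` (named, multiplicative emergence ratio vs control;
#'   control entry must be 1), `block_sd` (SD of log-scale block effects),
#'   `nb_dispersion` (NB2 theta; variance = mu + mu^2/theta),
#'   `depth_model` / `distance_model` (per-outcome location/scale lists),
#'   `community_taxon_means` (named expected counts per taxon),
#'   `community_effect` (named per-treatment multiplier, 1 = null).
#' @param defaults_file Path to a JSON defaults document; the packaged file
#'   is used when `NULL`.
#'
#' @return An object of class `simulation_config` (a validated named list).
#' @examples
#' cfg <- simulation_config(seed = 1, n_blocks = 5)
#' cfg$rate_ratios[["nematodes"]]
#' @export
simulation_config <- function(..., defaults_file = NULL) {
  if (is.null(defaults_file)) {
    defaults_file <- system.file("extdata", "sim-defaults.json",
                                 package = "blisstrial", mustWork = TRUE)
  }
  cfg <- jsonlite::read_json(defaults_file, simplifyVector = TRUE)
  cfg$comment <- NULL
  overrides <- list(...)
  if (length(overrides) > 0) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("all configuration overrides must be named", call. = FALSE)
    }
    for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  }
  # outcome_probs arrive as a list/matrix from JSON; normalise to a named
  # list of named numeric vectors over the outcome levels
  cfg$outcome_probs <- lapply(cfg$outcome_probs, function(p) {
    p <- unlist(p, use.names = FALSE)
    stats::setNames(as.numeric(p), outcome_levels()[seq_along(p)])
  })
  cfg$stage_probs <- stats::setNames(as.numeric(unlist(cfg$stage_probs)),
                                     stage_levels())
  cfg$rate_ratios <- unlist(cfg$rate_ratios)
  cfg$community_taxon_means <- unlist(cfg$community_taxon_means)
  cfg$community_effect <- unlist(cfg$community_effect)
  cfg$outcome_levels <- NULL
  cfg$stage_levels <- NULL
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the invariants the generators rely on: probability vectors
#' non-negative and summing to 1 within 1e-9, a unit rate ratio for the
#' control arm, positive NB dispersion, non-negative block SD and
#' non-negative community means. Called by [simulation_config()]; exported
#' so hand-built configurations can be checked too.
#'
#' @param cfg A `simulation_config` object or compatible list.
#' @return `cfg`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_simulation_config <- function(cfg) {
  check_simplex <- function(p, what) {
    if (any(!is.finite(p)) || any(p < 0)) {
      stop(what, " must be non-negative and finite", call. = FALSE)
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop(what, " must sum to 1 (got ", format(sum(p), digits = 12), ")",
           call. = FALSE)
    }
  }
  if (length(cfg$treatments) < 1 || cfg$treatments[1] != "control") {
    stop("treatments must list 'control' first", call. = FALSE)
  }
  missing_p <- setdiff(cfg$treatments, names(cfg$outcome_probs))
  if (length(missing_p) > 0) {
    stop("outcome_probs missing for treatment(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  for (tr in cfg$treatments) {
    check_simplex(cfg$outcome_probs[[tr]], paste0("outcome_probs[", tr, "]"))
  }
  check_simplex(cfg$stage_probs, "stage_probs")
  if (!isTRUE(all.equal(unname(cfg$rate_ratios[["control"]]), 1))) {
    stop("rate_ratios entry for control must equal 1", call. = FALSE)
  }
  if (any(cfg$rate_ratios <= 0)) {
    stop("rate_ratios must be positive", call. = FALSE)
  }
  if (!is.finite(cfg$nb_dispersion) || cfg$nb_dispersion <= 0) {
    stop("nb_dispersion must be > 0", call. = FALSE)
  }
  if (!is.finite(cfg$block_sd) || cfg$block_sd < 0) {
    stop("block_sd must be >= 0", call. = FALSE)
  }
  if (any(cfg$community_taxon_means < 0)) {
    stop("community_taxon_means must be non-negative", call. = FALSE)
  }
  if (any(cfg$community_effect < 0)) {
    stop("community_effect must be non-negative", call. = FALSE)
  }
  if (cfg$weevils_per_stump < 0) {
    stop("weevils_per_stump must be non-negative", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation configuration (seed ", x$seed, ", ", x$n_blocks,
      " blocks)\n", sep = "")
  cat("  treatments:", paste(x$treatments, collapse = ", "), "\n")
  cat("  emergence: intercept ", format(x$emergence_intercept, digits = 4),
      " (control mean ", format(exp(x$emergence_intercept), digits = 4),
      "), theta ", x$nb_dispersion, ", block SD ", x$block_sd, "\n", sep = "")
  cat("  rate ratios:",
      paste(names(x$rate_ratios), format(x$rate_ratios, digits = 3),
            sep = "=", collapse = ", "), "\n")
  cat("  community taxa:", length(x$community_taxon_means), "\n")
  invisible(x)
}

# Independent substream seed per dataset, derived from the root seed by a
# fixed dataset index so adding a dataset never perturbs another's stream.
# Kept below 2^31 - 1.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 1299709 * index) %% 2147483629)
}
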