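#' Rounding helpers for paper-style display
#'
#' Fixed-width rounding used by the report renderer: chi-square statistics
#' at 2 decimals, Cramer's V at 3, Bliss quantities at 4, and p-values
#' floored at `"<0.001"`.
#'
#' @param x Numeric value(s).
#' @param digits Decimal places.
#' @return Character vector.
#' @name formatting
NULL

#' @rdname formatting
#' @export
format_round <- function(x, digits) {
  formatC(round(x, digits), format = "f", digits = digits)
}

#' @rdname formatting
#' @export
format_p <- function(x, digits = 3, floor = 0.001) {
  ifelse(x < floor, paste0("<", format(floor, scientific = FALSE)),
         format_round(x, digits))
}

#' Render analysis results as display tables
#'
#' Turns result objects into character data.frames rounded for
#' side-by-side comparison with published tables: chi-square statistics at
#' 2 d.p., Cramer's V at 3 d.p., Bliss quantities at 4 d.p., p-values
#' floored at `"<0.001"`.
#'
#' @param x A `chisq_result`, `bliss_analysis`, `dunnett_contrasts` or
#'   `mrpp_result`.
#' @param ... Unused.
#' @return A data.frame of character columns.
#' @export
render_report <- function(x, ...) UseMethod("render_report")

#' @export
render_report.chisq_result <- function(x, ...) {
  data.frame(statistic = format_round(x$statistic, 2),
             df = as.character(x$df),
             p = format_p(x$p),
             cramers_v = format_round(x$cramers_v, 3),
             n = as.character(x$n))
}

#' @export
render_report.bliss_analysis <- function(x, ...) {
  df <- as.data.frame(x)
  data.frame(scope = df$scope,
             i_nf = format_round(df$i_nf, 4),
             i_bliss = format_round(df$i_bliss, 4),
             chi2_bliss = format_round(df$chi2_bliss, 4),
             p = format_p(df$p, digits = 4),
             S = format_round(df$S, 4),
             verdict = df$verdict)
}

#' @export
render_report.dunnett_contrasts <- function(x, ...) {
  df <- as.data.frame(x)
  data.frame(contrast = df$contrast,
             ratio = format_round(df$ratio, 3),
             se = format_round(df$se, 3),
             p_adjusted = format_p(df$p_adjusted))
}

#' @export
render_report.mrpp_result <- function(x, ...) {
  data.frame(A = format_round(x$A, 3), p = format_p(x$p),
             n_permutations = as.character(x$n_permutations))
}

#' Full Table-2-style contingency report
#'
#' Counts, both percentage breakdowns and the standardized residual (Z)
#' matrix of a cross-tabulation, stacked into one long data.frame for CSV
#' export.
#'
#' @param tab A `crosstab`.
#' @param result Matching [chi_square_independence()] result.
#' @return Data.frame with one row per (row level, quantity) pair.
#' @export
render_crosstab_report <- function(tab, result) {
  quantities <- list(count = tab$counts,
                     pct_within_row = percent_breakdown(tab, "rows"),
                     pct_within_col = percent_breakdown(tab, "columns"),
                     z = result$residuals)
  out <- do.call(rbind, lapply(names(quantities), function(q) {
    m <- quantities[[q]]
    df <- as.data.frame(m)
    cbind(data.frame(level = rownames(m), quantity = q), df)
  }))
  out <- out[order(match(out$level, tab$row_labels)), ]
  rownames(out) <- NULL
  out
}

#' Run the whole analysis pipeline
#'
#' Executes the requested stages in order -- simulate, contingency, bliss,
#' emergence, community -- writing one CSV per dataset and per report plus
#' a JSON run manifest into `out_dir`. The simulate stage generates the
#' three synthetic datasets from `cfg`; later stages read them back from
#' disk, so the pipeline exercises the same CSV interfaces an analysis of
#' real field data would use. Re-running with an identical configuration
#' reproduces byte-identical outputs (the manifest records seeds and
#' input-file checksums but no wall-clock times).
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory.
#' @param stages Subset of
#'   `c("simulate", "contingency", "bliss", "emergence", "community")`.
#' @param n_permutations MRPP permutation count.
#' @param n_mc Monte Carlo draws for the Dunnett adjustment.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @examples
#' \donttest{
#' out <- run_pipeline(simulation_config(seed = 1), tempfile())
#' names(out$stages)
#' }
#' @export
run_pipeline <- function(cfg, out_dir,
                         stages = c("simulate", "contingency", "bliss",
                                    "emergence", "community"),
                         n_permutations = 999, n_mc = 1e4, quiet = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  validate_simulation_config(cfg)
  analysis <- setdiff(stages, "simulate")
  if (length(analysis) > 0 && !"simulate" %in% stages) {
    needed <- c(contingency = "destructive.csv", bliss = "destructive.csv",
                emergence = "emergence.csv", community = "community.csv")
    missing_in <- setdiff(unique(needed[analysis]),
                          list.files(out_dir))
    if (length(missing_in) > 0) {
      stop("missing input file(s) for requested stage(s): ",
           paste(missing_in, collapse = ", "), call. = FALSE)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "blisstrial",
                   version = as.character(utils::packageVersion("blisstrial")),
                   seed = cfg$seed, stages = list())
  log_stage <- function(name, t0, files) {
    if (!quiet) {
      message(sprintf("[%s] wrote %s (%.2fs)", name,
                      paste(basename(files), collapse = ", "),
                      as.numeric(Sys.time()) - t0))
    }
  }
  if ("simulate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    paths <- write_simulated_datasets(cfg, out_dir)
    manifest$stages$simulate <- list(
      seed = cfg$seed,
      files = as.list(unname(vapply(paths, basename, character(1)))),
      md5 = as.list(unname(tools::md5sum(paths))))
    log_stage("simulate", t0, paths)
  }
  if ("contingency" %in% stages) {
    t0 <- as.numeric(Sys.time())
    rec <- read_destructive_csv(file.path(out_dir, "destructive.csv"))
    files <- character(0)
    for (rowf in c("treatment", "stage")) {
      tab <- build_crosstab(rec, rowf, "outcome", drop_empty = TRUE)
      res <- chi_square_independence(tab)
      f1 <- file.path(out_dir, paste0("contingency_", rowf, ".csv"))
      utils::write.csv(render_crosstab_report(tab, res), f1,
                       row.names = FALSE)
      f2 <- file.path(out_dir, paste0("contingency_", rowf, "_test.csv"))
      utils::write.csv(render_report(res), f2, row.names = FALSE)
      files <- c(files, f1, f2)
    }
    f3 <- file.path(out_dir, "depth_distance_summary.csv")
    utils::write.csv(rbind(
      cbind(field = "depth_cm", describe_by_group(rec, "depth_cm")),
      cbind(field = "dist_bole_cm", describe_by_group(rec, "dist_bole_cm"))),
      f3, row.names = FALSE)
    files <- c(files, f3)
    manifest$stages$contingency <- list(
      input_md5 = unname(tools::md5sum(file.path(out_dir,
                                                 "destructive.csv"))),
      files = as.list(basename(files)))
    log_stage("contingency", t0, files)
  }
  if ("bliss" %in% stages) {
    t0 <- as.numeric(Sys.time())
    rec <- read_destructive_csv(file.path(out_dir, "destructive.csv"))
    bl <- withCallingHandlers(
      run_bliss_analysis(rec, by_block = TRUE),
      warning = function(w) {
        if (!quiet) message("[bliss] ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    f <- file.path(out_dir, "bliss.csv")
    utils::write.csv(render_report(bl), f, row.names = FALSE)
    manifest$stages$bliss <- list(
      input_md5 = unname(tools::md5sum(file.path(out_dir,
                                                 "destructive.csv"))),
      files = list(basename(f)))
    log_stage("bliss", t0, f)
  }
  if ("emergence" %in% stages) {
    t0 <- as.numeric(Sys.time())
    em <- read_emergence_csv(file.path(out_dir, "emergence.csv"))
    full <- fit_nb(em, include_treatment = TRUE)
    null <- fit_nb(em, include_treatment = FALSE)
    lrt <- lrt_treatment(full, null)
    ctr <- dunnett_contrasts(full, n_mc = n_mc, seed = cfg$seed)
    emm <- marginal_means(full)
    f1 <- file.path(out_dir, "emergence_model.csv")
    utils::write.csv(
      data.frame(lrt_chi2 = format_round(lrt$chi2, 3), df = lrt$df,
                 p = format_p(lrt$p), theta = format_round(full$theta, 3)),
      f1, row.names = FALSE)
    f2 <- file.path(out_dir, "emergence_contrasts.csv")
    utils::write.csv(render_report(ctr), f2, row.names = FALSE)
    f3 <- file.path(out_dir, "emergence_emmeans.csv")
    utils::write.csv(
      data.frame(treatment = emm$treatment,
                 mean = format_round(emm$mean, 2),
                 se = format_round(emm$se, 2)), f3, row.names = FALSE)
    manifest$stages$emergence <- list(
      input_md5 = unname(tools::md5sum(file.path(out_dir,
                                                 "emergence.csv"))),
      n_mc = n_mc, files = as.list(basename(c(f1, f2, f3))))
    log_stage("emergence", t0, c(f1, f2, f3))
  }
  if ("community" %in% stages) {
    t0 <- as.numeric(Sys.time())
    cm <- read_community_csv(file.path(out_dir, "community.csv"))
    dm <- distance_matrix(cm)
    rows <- list()
    for (gv in c("treatment", "block")) {
      res <- mrpp(dm, cm[[gv]], n_permutations = n_permutations,
                  seed = cfg$seed)
      rows[[gv]] <- cbind(data.frame(grouping = gv), render_report(res))
    }
    f1 <- file.path(out_dir, "community_mrpp.csv")
    utils::write.csv(do.call(rbind, rows), f1, row.names = FALSE)
    ord <- pcoa(dm, n_axes = 2)
    f2 <- file.path(out_dir, "community_pcoa.csv")
    utils::write.csv(
      cbind(data.frame(trap = cm$traps, block = cm$block,
                       treatment = cm$treatment),
            as.data.frame(ord$coordinates, row.names = FALSE)),
      f2, row.names = FALSE)
    ra <- richness_abundance(cm)
    aov_ab <- oneway_anova(ra$abundance, ra$treatment)
    aov_ri <- oneway_anova(ra$richness, ra$treatment)
    f3 <- file.path(out_dir, "community_anova.csv")
    utils::write.csv(
      data.frame(response = c("abundance", "richness"),
                 F = format_round(c(aov_ab$F, aov_ri$F), 3),
                 p = format_p(c(aov_ab$p, aov_ri$p))),
      f3, row.names = FALSE)
    manifest$stages$community <- list(
      input_md5 = unname(tools::md5sum(file.path(out_dir,
                                                 "community.csv"))),
      n_permutations = n_permutations,
      files = as.list(basename(c(f1, f2, f3))))
    log_stage("community", t0, c(f1, f2, f3))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read pipeline CSV inputs
#'
#' Readers for the three delimited formats the pipeline exchanges:
#' destructive-sampling records (`block, treatment, stage, outcome,
#' depth_cm, dist_bole_cm`), emergence counts (`block, treatment,
#' emerged`) and community matrices (`trap, block, treatment`, one column
#' per taxon).
#'
#' @param path CSV file path.
#' @return A data.frame of records ([read_destructive_csv()],
#'   [read_emergence_csv()]) or a [community_matrix()]
#'   ([read_community_csv()]).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_destructive_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("block", "treatment", "stage", "outcome")
  if (!all(needed %in% names(df))) {
    stop("destructive CSV must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname pipeline_io
#' @export
read_emergence_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("block", "treatment", "emerged") %in% names(df))) {
    stop("emergence CSV must have columns block, treatment, emerged",
         call. = FALSE)
  }
  df
}

#' @rdname pipeline_io
#' @param granularity Granularity label for the community matrix.
#' @export
read_community_csv <- function(path, granularity = "broad") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("trap", "block", "treatment")
  if (!all(meta %in% names(df))) {
    stop("community CSV must have columns trap, block, treatment",
         call. = FALSE)
  }
  taxa <- setdiff(names(df), meta)
  community_matrix(as.matrix(df[taxa]), block = df$block,
                   treatment = df$treatment, traps = df$trap,
                   granularity = granularity)
}

#' Packaged field-trial summary tables
#'
#' The published aggregate tables of the Scottish 2022 trial, shipped as
#' plain CSV: the treatment-by-outcome and stage-by-outcome
#' cross-tabulation counts, and the per-block observed/expected combined
#' infection rates of the Bliss analysis. These are the inputs for the
#' package's reproduction of the published statistics.
#'
#' @param which One of `"treatment_outcome"`, `"stage_outcome"`,
#'   `"bliss_blocks"`.
#' @return For the two count tables, a `crosstab`; for `"bliss_blocks"`, a
#'   data.frame with `scope`, `i_nf`, `i_bliss`.
#' @examples
#' chi_square_independence(scotland2022_table("treatment_outcome"))
#' @export
scotland2022_table <- function(which = c("treatment_outcome",
                                         "stage_outcome", "bliss_blocks")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("scotland2022_", which, ".csv"),
                      package = "blisstrial", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  switch(which,
    treatment_outcome = as_crosstab(df, "treatment", "outcome"),
    stage_outcome = as_crosstab(df, "stage", "outcome"),
    bliss_blocks = df)
}

#' Expand a cross-tabulation into record-level rows
#'
#' Inverse of [build_crosstab()] for aggregate-only data: emits one record
#' per count, with the two tabulated fields filled in and the remaining
#' record fields `NA`. Used to push published count tables through
#' record-level operations such as [run_bliss_analysis()].
#'
#' @param tab A `crosstab` whose factors are record fields.
#' @return A weevil-record data.frame.
#' @export
crosstab_to_records <- function(tab) {
  stopifnot(inherits(tab, "crosstab"))
  idx <- which(tab$counts > 0, arr.ind = TRUE)
  reps <- tab$counts[idx]
  out <- data.frame(block = NA_character_, treatment = NA_character_,
                    stage = NA_character_, outcome = NA_character_,
                    depth_cm = NA_real_, dist_bole_cm = NA_real_,
                    stringsAsFactors = FALSE)[rep(1, sum(reps)), ]
  out[[tab$row_factor]] <- rep(tab$row_labels[idx[, 1]], reps)
  out[[tab$col_factor]] <- rep(tab$col_labels[idx[, 2]], reps)
  rownames(out) <- NULL
  out
}
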