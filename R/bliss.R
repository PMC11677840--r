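#' Infection rate of one treatment arm
#'
#' Proportion of destructively sampled weevils counted as infected/dead in
#' a treatment arm. Two mortality definitions:
#' \describe{
#'   \item{`any_death`}{outcome is anything but `alive` (includes
#'     indeterminate deaths); this is the definition under which the
#'     published pooled rates reproduce.}
#'   \item{`agent_specific`}{only the matching agent's kill counts --
#'     `fungus_killed` for the fungus arm, `nematode_killed` for the
#'     nematode arm, either agent kill (but not indeterminate) for the
#'     combined and control arms.}
#' }
#'
#' @param records Weevil record data.frame.
#' @param treatment Arm label (one of [treatment_levels()]).
#' @param mortality `"any_death"` (default) or `"agent_specific"`.
#' @return A proportion in \[0, 1\].
#' @export
infection_rate <- function(records, treatment,
                           mortality = c("any_death", "agent_specific")) {
  mortality <- match.arg(mortality)
  treatment <- match.arg(treatment, treatment_levels())
  oc <- record_factor(records$outcome, "outcome")
  sel <- records$treatment == treatment
  if (!any(sel)) {
    stop("no records for treatment '", treatment, "'", call. = FALSE)
  }
  oc <- oc[sel]
  dead <- switch(mortality,
    any_death = oc != "alive",
    agent_specific = switch(treatment,
      fungi = oc == "fungus_killed",
      nematodes = oc == "nematode_killed",
      oc %in% c("nematode_killed", "fungus_killed")))
  mean(dead)
}

#' Convert a full-dose infection rate to a half-dose rate
#'
#' The combined treatment applies each agent at half its standalone dose,
#' but the trial has no half-dose-alone arms. The default `"linear"`
#' convention estimates the half-dose rate as half the full-dose rate;
#' `"full"` uses the full-dose rate unchanged (a conservative sensitivity
#' setting).
#'
#' @param full_dose_rate Proportion in \[0, 1\].
#' @param convention `"linear"` (default) or `"full"`.
#' @return A proportion.
#' @export
half_dose_rate <- function(full_dose_rate, convention = c("linear", "full")) {
  convention <- match.arg(convention)
  if (any(full_dose_rate < 0 | full_dose_rate > 1)) {
    stop("full_dose_rate must lie in [0, 1]", call. = FALSE)
  }
  switch(convention, linear = full_dose_rate / 2, full = full_dose_rate)
}

#' Expected combined infection rate under Bliss independence
#'
#' Under Bliss independence the two agents act on independent "targets",
#' so survival probabilities multiply and the expected combined infection
#' rate is `I_EPF + I_EPN - I_EPF * I_EPN`. Symmetric in its arguments,
#' monotone in each, and bounded by
#' `max(I_EPF, I_EPN) <= I_Bliss <= min(1, I_EPF + I_EPN)`.
#'
#' @param i_epf,i_epn Half-dose infection rates of the fungus and nematode
#'   agents, proportions in \[0, 1\].
#' @return The expected combined proportion.
#' @examples
#' bliss_expected(0.1509, 0.2686) # ~0.3790
#' @export
bliss_expected <- function(i_epf, i_epn) {
  if (any(c(i_epf, i_epn) < 0 | c(i_epf, i_epn) > 1)) {
    stop("infection rates must lie in [0, 1]", call. = FALSE)
  }
  i_epf + i_epn - i_epf * i_epn
}

#' Bliss deviation test
#'
#' Measures the departure of the observed combined infection rate from
#' the Bliss expectation with the statistic
#' `Chi2_Bliss = (I_NF - I_Bliss)^2 / I_Bliss`, referred to a chi-square
#' distribution with 1 df (upper tail).
#'
#' @param i_nf Observed combined-arm infection proportion.
#' @param i_bliss Expected proportion from [bliss_expected()].
#' @return List with `chi2` and `p`. A zero expectation with a non-zero
#'   observation is a defined failure (statistic unbounded); with a zero
#'   observation it yields `chi2 = 0, p = 1`.
#' @examples
#' bliss_test(0.5463, 0.3790)
#' @export
bliss_test <- function(i_nf, i_bliss) {
  stopifnot(length(i_nf) == 1, length(i_bliss) == 1)
  if (i_bliss == 0) {
    if (i_nf > 0) {
      stop("Bliss expectation is 0 with a positive observed rate: ",
           "deviation statistic unbounded", call. = FALSE)
    }
    return(list(chi2 = 0, p = 1))
  }
  chi2 <- (i_nf - i_bliss)^2 / i_bliss
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Synergy score and verdict
#'
#' The synergy score is `S = I_NF - I_Bliss`; a positive score means the
#' combined treatment killed more than independence predicts (synergy), a
#' negative score less (antagonism). The verdict is taken strictly by sign
#' by default (`tolerance = 0`); a positive tolerance widens the
#' `Additive` band to `|S| <= tolerance`.
#'
#' @param i_nf,i_bliss Observed and expected combined proportions.
#' @param tolerance Half-width of the additive band (default 0).
#' @return List with `S` and `verdict` (one of `"Synergy"`, `"Additive"`,
#'   `"Antagonist"`).
#' @export
classify_synergy <- function(i_nf, i_bliss, tolerance = 0) {
  stopifnot(tolerance >= 0)
  s <- i_nf - i_bliss
  verdict <- if (s > tolerance) "Synergy"
             else if (s < -tolerance) "Antagonist"
             else "Additive"
  list(S = s, verdict = verdict)
}

#' Full Bliss independence analysis of a combined treatment
#'
#' Runs the whole synergy procedure on destructive-sampling records:
#' estimates the observed combined-arm infection rate `I_NF` from the
#' `halfmix` arm, derives half-dose agent rates `I_EPF`/`I_EPN` from the
#' full-dose `fungi` and `nematodes` arms via the chosen convention,
#' forms the Bliss expectation, and reports the deviation statistic,
#' p-value, synergy score and verdict -- pooled over all records and,
#' optionally, within each block. Blocks missing any of the three required
#' arms are skipped with a warning.
#'
#' @param records Weevil record data.frame with `block`, `treatment`,
#'   `outcome`.
#' @param by_block Also analyse each block separately.
#' @param mortality Passed to [infection_rate()].
#' @param half_dose_convention Passed to [half_dose_rate()].
#' @param tolerance Passed to [classify_synergy()].
#' @return A data.frame of class `bliss_analysis`, one row per scope
#'   (`"Total"` first, then blocks): `scope`, `n_halfmix`, `i_epf`,
#'   `i_epn`, `i_nf`, `i_bliss`, `chi2_bliss`, `p`, `S`, `verdict`.
#' @examples
#' rec <- simulate_destructive(simulation_config(seed = 3))
#' run_bliss_analysis(rec)
#' @export
run_bliss_analysis <- function(records, by_block = FALSE,
                               mortality = "any_death",
                               half_dose_convention = "linear",
                               tolerance = 0) {
  needed <- c("fungi", "nematodes", "halfmix")
  have <- unique(records$treatment)
  if (!all(needed %in% have)) {
    stop("records must contain the fungi, nematodes and halfmix arms",
         call. = FALSE)
  }
  one_scope <- function(rec, scope) {
    i_epf <- half_dose_rate(infection_rate(rec, "fungi", mortality),
                            half_dose_convention)
    i_epn <- half_dose_rate(infection_rate(rec, "nematodes", mortality),
                            half_dose_convention)
    i_nf <- infection_rate(rec, "halfmix", mortality)
    i_bliss <- bliss_expected(i_epf, i_epn)
    tst <- bliss_test(i_nf, i_bliss)
    cls <- classify_synergy(i_nf, i_bliss, tolerance)
    data.frame(scope = scope, n_halfmix = sum(rec$treatment == "halfmix"),
               i_epf = i_epf, i_epn = i_epn, i_nf = i_nf, i_bliss = i_bliss,
               chi2_bliss = tst$chi2, p = tst$p, S = cls$S,
               verdict = cls$verdict, stringsAsFactors = FALSE)
  }
  out <- one_scope(records, "Total")
  if (by_block) {
    for (b in sort(unique(as.character(records$block)))) {
      rec_b <- records[records$block == b, , drop = FALSE]
      missing_arms <- setdiff(needed, unique(rec_b$treatment))
      if (length(missing_arms) > 0) {
        warning("block ", b, " skipped: no records for arm(s) ",
                paste(missing_arms, collapse = ", "), call. = FALSE)
        next
      }
      out <- rbind(out, one_scope(rec_b, b))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("bliss_analysis", "data.frame")
  out
}

#' @export
print.bliss_analysis <- function(x, digits = 4, ...) {
  cat("Bliss independence analysis (combined half-dose treatment)\n")
  df <- as.data.frame(x)
  num <- c("i_epf", "i_epn", "i_nf", "i_bliss", "chi2_bliss", "p", "S")
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
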