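#' Controlled vocabularies for trial records
#'
#' The destructive-sampling analysis uses closed label sets: four treatments
#' (untreated control, full-dose entomopathogenic fungus, half-dose
#' fungus-plus-nematode mix, full-dose entomopathogenic nematode), three
#' developmental stages, and four infection outcomes. Level order is fixed
#' (control first) so that model coefficients and table rows are comparable
#' across runs.
#'
#' @return A character vector of levels, in canonical order.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
treatment_levels <- function() c("control", "fungi", "halfmix", "nematodes")

#' @rdname vocabularies
#' @export
stage_levels <- function() c("larva", "pupa", "adult")

#' @rdname vocabularies
#' @export
outcome_levels <- function() {
  c("alive", "nematode_killed", "fungus_killed", "indeterminate")
}

# Coerce a record column to a factor over its declared vocabulary, erroring
# on labels outside it. Block labels are open: sorted unique values.
record_factor <- function(x, field) {
  vocab <- switch(field,
    treatment = treatment_levels(),
    stage = stage_levels(),
    outcome = outcome_levels(),
    block = sort(unique(as.character(x))),
    stop("'", field, "' is not a categorical record field", call. = FALSE)
  )
  x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), vocab)
  if (length(bad) > 0) {
    stop("unknown ", field, " label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = vocab)
}
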