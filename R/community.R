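#' Trap-by-taxon community matrix
#'
#' Container for non-target invertebrate counts: one row per trap (with
#' block and treatment attributes), one column per taxon, at either broad
#' (order-level) or narrow (family/species-level) granularity.
#'
#' @param counts Non-negative numeric matrix, traps in rows, taxa in
#'   columns (column names are taxon labels).
#' @param block,treatment Per-trap grouping labels.
#' @param traps Trap labels; must be unique.
#' @param granularity `"broad"` or `"narrow"`.
#' @return An object of class `community_matrix`.
#' @export
community_matrix <- function(counts, block, treatment, traps = NULL,
                             granularity = c("broad", "narrow")) {
  granularity <- match.arg(granularity)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(traps)) traps <- paste0("trap", seq_len(nrow(counts)))
  if (anyDuplicated(traps)) stop("duplicate trap labels", call. = FALSE)
  stopifnot(length(block) == nrow(counts),
            length(treatment) == nrow(counts))
  rownames(counts) <- traps
  structure(list(counts = counts, traps = as.character(traps),
                 block = as.character(block),
                 treatment = as.character(treatment),
                 taxa = colnames(counts), granularity = granularity),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("Community matrix (", x$granularity, " taxa): ", nrow(x$counts),
      " traps x ", ncol(x$counts), " taxa\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.community_matrix <- function(x, ...) {
  cbind(data.frame(trap = x$traps, block = x$block,
                   treatment = x$treatment, stringsAsFactors = FALSE),
        as.data.frame(x$counts, row.names = seq_along(x$traps)))
}

#' Pairwise distances between traps
#'
#' Standard community distance metrics: Bray-Curtis on raw counts,
#' Sorensen (Bray-Curtis on presence/absence; the package default for
#' ordination and MRPP), or Euclidean on raw counts. A pair of all-zero
#' traps has an undefined Bray-Curtis/Sorensen distance; it is defined
#' here as 0 with a warning.
#'
#' @param m A [community_matrix()].
#' @param metric `"sorensen"`, `"bray_curtis"` or `"euclidean"`.
#' @return An object of class `distance_matrix`: full symmetric matrix
#'   `d` with zero diagonal, trap `labels`, and the `metric` name.
#' @export
distance_matrix <- function(m, metric = c("sorensen", "bray_curtis",
                                          "euclidean")) {
  stopifnot(inherits(m, "community_matrix"))
  metric <- match.arg(metric)
  if (nrow(m$counts) < 2) stop("need at least 2 traps", call. = FALSE)
  # vegdist warns generically about empty rows; the specific all-zero-pair
  # warning is raised below instead
  d <- switch(metric,
    bray_curtis = suppressWarnings(
      vegan::vegdist(m$counts, method = "bray")),
    sorensen = suppressWarnings(
      vegan::vegdist(m$counts, method = "bray", binary = TRUE)),
    euclidean = stats::dist(m$counts))
  d <- as.matrix(d)
  if (any(!is.finite(d))) {
    warning("all-zero trap pair(s): ", metric,
            " distance undefined, set to 0", call. = FALSE)
    d[!is.finite(d)] <- 0
  }
  diag(d) <- 0
  dimnames(d) <- list(m$traps, m$traps)
  structure(list(d = d, labels = m$traps, metric = metric,
                 block = m$block, treatment = m$treatment),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("Distance matrix (", x$metric, "): ", nrow(x$d), " traps\n", sep = "")
  invisible(x)
}

#' Principal co-ordinates analysis
#'
#' Metric multidimensional scaling: the squared distance matrix is double
#' centred (`-1/2 D^2` about row/column means) and eigendecomposed;
#' co-ordinates are eigenvectors scaled by the square root of their
#' (positive) eigenvalues. Negative eigenvalues -- which arise for
#' non-Euclidean metrics such as Sorensen -- are reported but their axes
#' dropped; no Cailliez/Lingoes correction is applied.
#'
#' @param dm A [distance_matrix()].
#' @param n_axes Number of axes to keep (default: all positive-eigenvalue
#'   axes). Requests beyond the positive count are truncated with a
#'   warning.
#' @return An object of class `pcoa_result`: `coordinates` (traps x
#'   axes), `eigenvalues` (all, descending), `prop_explained` (per kept
#'   axis, relative to the positive eigenvalue total), and
#'   `n_negative`/`negative_sum` summarising the negative spectrum.
#' @export
pcoa <- function(dm, n_axes = NULL) {
  stopifnot(inherits(dm, "distance_matrix"))
  n <- nrow(dm$d)
  mds <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dm$d), k = n - 1, eig = TRUE))
  eig <- sort(mds$eig, decreasing = TRUE)
  pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  if (is.null(n_axes)) n_axes <- pos
  if (n_axes > pos) {
    warning("only ", pos, " positive-eigenvalue axes available; truncating",
            call. = FALSE)
    n_axes <- pos
  }
  coords <- if (n_axes > 0) mds$points[, seq_len(n_axes), drop = FALSE]
            else matrix(0, n, 0)
  rownames(coords) <- dm$labels
  if (n_axes > 0) colnames(coords) <- paste0("PCoA", seq_len(n_axes))
  pos_sum <- sum(eig[eig > 0])
  structure(
    list(coordinates = coords, eigenvalues = eig,
         prop_explained = if (pos_sum > 0 && n_axes > 0)
           eig[seq_len(n_axes)] / pos_sum else numeric(0),
         n_negative = sum(eig < 0), negative_sum = sum(eig[eig < 0]),
         metric = dm$metric),
    class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA on ", x$metric, " distances: ", nrow(x$coordinates),
      " traps, ", ncol(x$coordinates), " axes kept\n", sep = "")
  if (length(x$prop_explained) > 0) {
    cat("  first axes explain ",
        paste0(round(100 * utils::head(x$prop_explained, 3), 1), "%",
               collapse = ", "), "\n", sep = "")
  }
  if (x$n_negative > 0) {
    cat("  ", x$n_negative, " negative eigenvalues (sum ",
        format(x$negative_sum, digits = 3), "), axes dropped\n", sep = "")
  }
  invisible(x)
}

#' Multi-response permutation procedure (MRPP)
#'
#' Tests whether a grouping (treatment or block) structures the community
#' by comparing the weighted mean within-group distance
#' `delta = sum_g (n_g / N) * mean(within-group pairwise distances)`
#' against its Monte Carlo permutation null (random relabelling that
#' preserves group sizes). Reports the chance-corrected within-group
#' agreement `A = 1 - delta_observed / delta_expected` (0 in expectation
#' under random grouping, 1 for identical within-group units) and the
#' add-one Monte Carlo p-value, which is never exactly zero.
#'
#' @param dm A [distance_matrix()].
#' @param grouping Per-trap group labels (>= 2 groups, each with >= 2
#'   members).
#' @param n_permutations Number of random permutations (default 9999).
#' @param seed Seed for the permutation stream.
#' @param weight Group weights in delta: `"n"` for `n_g / N` (default) or
#'   `"n_minus_1"` for `(n_g - 1) / sum(n_g - 1)`.
#' @return An object of class `mrpp_result`: `delta_observed`,
#'   `delta_expected`, `A`, `p`, `n_permutations`, `seed`. When every
#'   distance is zero (`delta_expected = 0`), `A` is defined as 0 and
#'   `p = 1`.
#' @examples
#' cm <- simulate_community(simulation_config(seed = 5))
#' mrpp(distance_matrix(cm), cm$treatment, n_permutations = 999)
#' @export
mrpp <- function(dm, grouping, n_permutations = 9999, seed = 1,
                 weight = c("n", "n_minus_1")) {
  stopifnot(inherits(dm, "distance_matrix"))
  weight <- match.arg(weight)
  g <- factor(grouping)
  if (length(g) != nrow(dm$d)) {
    stop("grouping length must match the number of traps", call. = FALSE)
  }
  sizes <- table(g)
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2)) {
    stop("singleton group(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  w <- switch(weight,
              n = as.numeric(sizes) / length(g),
              n_minus_1 = (as.numeric(sizes) - 1) / sum(sizes - 1))
  delta_fun <- function(gg) {
    wd <- vapply(levels(g), function(l) {
      idx <- which(gg == l)
      sub <- dm$d[idx, idx]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    sum(w * wd)
  }
  delta_obs <- delta_fun(g)
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations),
                 function(i) delta_fun(sample(g)), numeric(1))
  delta_exp <- mean(perm)
  if (delta_exp == 0) {
    a <- 0
    p <- 1
  } else {
    a <- 1 - delta_obs / delta_exp
    p <- (1 + sum(perm <= delta_obs)) / (1 + n_permutations)
  }
  structure(list(delta_observed = delta_obs, delta_expected = delta_exp,
                 A = a, p = p, n_permutations = n_permutations,
                 seed = seed, weight = weight, metric = dm$metric),
            class = "mrpp_result")
}

#' @export
print.mrpp_result <- function(x, ...) {
  cat("MRPP (", x$metric, " distances, ", x$n_permutations,
      " permutations)\n", sep = "")
  cat("  delta observed ", format(x$delta_observed, digits = 4),
      ", expected ", format(x$delta_expected, digits = 4), "\n", sep = "")
  cat("  A = ", format(x$A, digits = 3), ", p = ",
      format(x$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical between/within mean-squares F test, used for per-trap total
#' abundance and taxon richness across treatments.
#'
#' @param values Numeric response.
#' @param grouping Group labels (>= 2 groups, at least one with >= 2
#'   values).
#' @return List with `F`, `df_between`, `df_within`, `p`.
#' @export
oneway_anova <- function(values, grouping) {
  g <- factor(grouping)
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (length(values) - nlevels(g) < 1) {
    stop("no within-group degrees of freedom", call. = FALSE)
  }
  tst <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(tst$statistic),
       df_between = unname(tst$parameter[1]),
       df_within = unname(tst$parameter[2]),
       p = unname(tst$p.value))
}

#' Per-trap abundance and richness
#'
#' Total abundance (row sum) and taxon richness (number of taxa with a
#' positive count) for every trap.
#'
#' @param m A [community_matrix()].
#' @return Data.frame with `trap`, `block`, `treatment`, `abundance`,
#'   `richness`.
#' @export
richness_abundance <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  data.frame(trap = m$traps, block = m$block, treatment = m$treatment,
             abundance = unname(rowSums(m$counts)),
             richness = unname(rowSums(m$counts > 0)),
             stringsAsFactors = FALSE)
}
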