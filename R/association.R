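#' Pearson product-moment correlation test
#'
#' Two-sided Pearson correlation with the p-value taken from the t reference
#' distribution on `n - 2` degrees of freedom, `t = r sqrt(n-2) / sqrt(1-r^2)`.
#' Thin contract-checked front end over [stats::cor.test()].
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, each with positive
#'   variance.
#' @return object of class `correlation_result`: list with `r`, `n`, `t`,
#'   `df`, `p`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("Pearson test needs at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation is undefined for a constant vector", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), n = length(x),
                 t = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, t = %.3f on %d df, two-sided p = %.4g)\n",
              x$r, x$n, x$t, x$df, x$p))
  invisible(x)
}

#' Correlation between preference and performance diet breadths
#'
#' Tests, across species, whether the effective number of hosts in the
#' oviposition-preference profile tracks the effective number of hosts in
#' the larval-survival profile: a community-level mother-knows-best check on
#' the degree of specialisation itself.
#'
#' @param estimates an `alpha_distributions` object (both measures present).
#' @return `correlation_result` over the per-species mean alphas
#'   (preference vs performance).
#' @export
alpha_pref_perf_correlation <- function(estimates) {
  stopifnot(inherits(estimates, "alpha_distributions"))
  s <- estimates$summary
  pref <- s[s$measure == "eggs", , drop = FALSE]
  perf <- s[s$measure == "survival", , drop = FALSE]
  if (!setequal(pref$species, perf$species))
    stop("preference and performance estimates cover different species", call. = FALSE)
  perf <- perf[match(pref$species, perf$species), , drop = FALSE]
  pearson_test(pref$mean_alpha, perf$mean_alpha)
}

#' Per-species preference-performance correlation
#'
#' For one species, correlates its mean no-choice egg count with its larval
#' survival proportion across the host catalogue (the per-species
#' mother-knows-best test). Fruits without survival trials are dropped from
#' the pairing; unobserved egg cells count as zero (the design is complete).
#'
#' @param dataset a `community_dataset`.
#' @param species species name present in the roster.
#' @return `correlation_result` over the per-fruit (mean eggs, survival)
#'   pairs.
#' @export
species_pref_perf_correlation <- function(dataset, species) {
  stopifnot(inherits(dataset, "community_dataset"))
  if (!species %in% dataset$roster$species)
    stop(sprintf("species '%s' not in roster", species), call. = FALSE)
  eggs <- build_interaction_matrix(dataset, "eggs", "mean")[, species]
  surv <- suppressWarnings(build_interaction_matrix(dataset, "survival"))[, species]
  ok <- !is.na(surv)
  pearson_test(eggs[ok], surv[ok])
}

#' Choice vs no-choice preference consistency
#'
#' Checks that egg counts from single-fruit (no-choice) exposures are an
#' adequate substitute for the preference hierarchy expressed when fruits
#' are offered together. By default each choice-replicate egg count on a
#' subset fruit is paired with the species' per-fruit no-choice mean
#' (12 replicates x 8 fruits = 96 pairs under the standard design); the
#' `"fruit"` pairing collapses choice replicates to per-fruit means first
#' (8 pairs).
#'
#' @param dataset a `community_dataset`.
#' @param species species name.
#' @param pairing `"replicate"` (default) or `"fruit"`.
#' @return `correlation_result`.
#' @export
choice_nochoice_consistency <- function(dataset, species,
                                        pairing = c("replicate", "fruit")) {
  stopifnot(inherits(dataset, "community_dataset"))
  pairing <- match.arg(pairing)
  ov <- dataset$oviposition[dataset$oviposition$species == species, , drop = FALSE]
  ch <- ov[ov$assay == "choice", , drop = FALSE]
  nc <- ov[ov$assay == "no_choice", , drop = FALSE]
  subset_ids <- dataset$catalog$fruit_id[dataset$catalog$in_choice_subset]
  if (nrow(ch) == 0L)
    stop(sprintf("species '%s' has no choice records", species), call. = FALSE)
  if (!all(subset_ids %in% nc$fruit_id))
    stop(sprintf("species '%s' lacks no-choice coverage of the choice subset",
                 species), call. = FALSE)
  nc_mean <- tapply(nc$eggs, nc$fruit_id, mean)
  if (pairing == "replicate") {
    pearson_test(ch$eggs, unname(nc_mean[as.character(ch$fruit_id)]))
  } else {
    ch_mean <- tapply(ch$eggs, ch$fruit_id, mean)
    ids <- intersect(names(ch_mean), names(nc_mean))
    pearson_test(unname(ch_mean[ids]), unname(nc_mean[ids]))
  }
}
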