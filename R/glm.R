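#' Build a treatment-coded design matrix for an ordered term list
#'
#' Expands factor terms with treatment (reference-level) contrasts — the
#' reference being the first declared level — and interactions as columnwise
#' products, then drops aliased columns so the returned matrix has full
#' column rank. Dropped columns are recorded in the `dropped` element.
#'
#' @param terms character vector of term labels in model order, e.g.
#'   `c("survival", "guild", "survival:guild")`; `character(0)` gives the
#'   intercept-only design.
#' @param data data.frame holding the variables; factors must have at least
#'   two levels.
#' @return list with `X` (full-rank design matrix), `assign` (term index per
#'   column, 0 = intercept), `term_labels`, `dropped` (names of aliased
#'   columns removed).
#' @export
build_design_matrix <- function(terms, data) {
  stopifnot(is.character(terms), is.data.frame(data))
  for (v in names(data))
    if (is.factor(data[[v]]) && nlevels(droplevels(data[[v]])) < 2L &&
        any(vapply(terms, function(tt) v %in% strsplit(tt, ":")[[1]], logical(1))))
      stop(sprintf("factor '%s' has a single level", v), call. = FALSE)
  f <- if (length(terms)) stats::reformulate(terms, intercept = TRUE) else ~ 1
  mf <- stats::model.frame(f, data, drop.unused.levels = TRUE)
  X <- stats::model.matrix(f, mf)
  asg <- attr(X, "assign")
  qx <- qr(X)
  dropped <- character(0)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- colnames(X)[-keep]
    asg <- asg[keep]
    X <- X[, keep, drop = FALSE]
  }
  list(X = X, assign = asg,
       term_labels = attr(stats::terms(f), "term.labels"), dropped = dropped)
}

#' Fit a Poisson log-linear model with quasi-Poisson dispersion
#'
#' Iteratively reweighted least squares for the log-link Poisson mean model,
#' run to stationarity of the deviance (relative change below `tol` or
#' `maxit` iterations). The response may be non-integral (quasi-likelihood
#' accepts e.g. per-cell mean counts). The dispersion is the Pearson
#' chi-square divided by the residual degrees of freedom; fitted means are
#' floored at 1e-10 and a floor hit flags the fit.
#'
#' @param X full-rank design matrix (see [build_design_matrix()]).
#' @param y non-negative response vector.
#' @param tol relative deviance-change convergence tolerance.
#' @param maxit maximum IRLS iterations.
#' @return object of class `qp_fit`: `coefficients`, `fitted`, `deviance`
#'   (`2 * sum(y log(y/mu) - (y - mu))`, with `y log(y/mu) = 0` at `y = 0`),
#'   `df_residual`, `pearson`, `dispersion`, `converged`, `boundary`,
#'   `iterations`, `rank`.
#' @export
fit_quasipoisson <- function(X, y, tol = 1e-10, maxit = 100L) {
  stopifnot(is.matrix(X), is.numeric(y), nrow(X) == length(y))
  if (any(!is.finite(y)) || any(y < 0))
    stop("response must be non-negative and finite", call. = FALSE)
  n <- length(y)
  mu <- pmax(y, 0) + mean(y) / 2 + 0.1
  eta <- log(mu)
  dev <- qp_deviance(y, mu)
  converged <- FALSE
  boundary <- FALSE
  iter <- 0L
  while (iter < maxit) {
    iter <- iter + 1L
    z <- eta + (y - mu) / mu
    sw <- sqrt(mu)
    qx <- qr(X * sw)
    beta <- qr.coef(qx, z * sw)
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    if (any(mu < 1e-10)) {
      mu <- pmax(mu, 1e-10)
      boundary <- TRUE
    }
    dev_new <- qp_deviance(y, mu)
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  if (!converged)
    warning("IRLS did not converge within maxit iterations", call. = FALSE)
  rank <- qr(X)$rank
  df_res <- n - rank
  pearson <- sum((y - mu)^2 / mu)
  structure(list(coefficients = stats::setNames(drop(beta), colnames(X)),
                 fitted = mu, deviance = dev, df_residual = df_res,
                 pearson = pearson,
                 dispersion = if (df_res > 0) pearson / df_res else NaN,
                 converged = converged, boundary = boundary,
                 iterations = iter, rank = rank),
            class = "qp_fit")
}

qp_deviance <- function(y, mu) {
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(term - (y - mu))
}

#' @export
print.qp_fit <- function(x, ...) {
  cat(sprintf("quasi-Poisson fit: deviance %.4f on %d df, dispersion %.3f%s\n",
              x$deviance, x$df_residual, x$dispersion,
              if (!x$converged) " (NOT converged)" else ""))
  invisible(x)
}

#' Sequential (type-I) quasi-Poisson analysis of deviance
#'
#' Fits the nested model sequence obtained by adding the declared terms one
#' at a time to the intercept-only model and reports, per term, the deviance
#' drop, its degrees of freedom, the residual df after inclusion, and a
#' dispersion-scaled test: `F = (ddev/ddf) / phi` with `phi` the Pearson
#' dispersion of the fullest model, referred to `F(ddf, df_residual_full)`
#' (or, with `pvalue = "chisq"`, `ddev/phi` referred to chi-square on
#' `ddf` df). Term order matters; rows read as `ddev_{ddf, df_residual}`.
#'
#' @param terms ordered character vector of term labels.
#' @param data observation table.
#' @param response name of the non-negative response column.
#' @param pvalue `"F"` (quasi-F, default) or `"chisq"` (scaled chi-square).
#' @return data.frame of class `deviance_table` with columns `term`,
#'   `delta_dev`, `delta_df`, `df_residual`, `F`, `p`; attributes
#'   `dispersion`, `df_residual_full`, `n_obs`, `response`, `pvalue`.
#' @export
sequential_deviance <- function(terms, data, response = "eggs",
                                pvalue = c("F", "chisq")) {
  pvalue <- match.arg(pvalue)
  stopifnot(length(terms) >= 1L, response %in% names(data))
  y <- data[[response]]
  fits <- vector("list", length(terms) + 1L)
  ranks <- integer(length(terms) + 1L)
  for (k in 0:length(terms)) {
    dm <- build_design_matrix(terms[seq_len(k)], data)
    fits[[k + 1L]] <- fit_quasipoisson(dm$X, y)
    ranks[k + 1L] <- fits[[k + 1L]]$rank
  }
  full <- fits[[length(fits)]]
  phi <- full$dispersion
  dd <- -diff(vapply(fits, `[[`, numeric(1), "deviance"))
  dd[dd < 0 & dd > -1e-8] <- 0
  ddf <- diff(ranks)
  df_after <- length(y) - cumsum(ddf) - 1L
  Fstat <- (dd / ddf) / phi
  p <- if (pvalue == "F")
    stats::pf(Fstat, ddf, full$df_residual, lower.tail = FALSE)
  else
    stats::pchisq(dd / phi, ddf, lower.tail = FALSE)
  p[ddf == 0] <- NA_real_
  out <- data.frame(term = terms, delta_dev = dd, delta_df = ddf,
                    df_residual = df_after, F = Fstat, p = p,
                    stringsAsFactors = FALSE)
  structure(out, dispersion = phi, df_residual_full = full$df_residual,
            n_obs = length(y), response = response, pvalue = pvalue,
            converged = all(vapply(fits, `[[`, logical(1), "converged")),
            class = c("deviance_table", "data.frame"))
}

#' @export
print.deviance_table <- function(x, ...) {
  cat(sprintf("Analysis of deviance (quasi-Poisson, dispersion %.3f, n = %d)\n",
              attr(x, "dispersion"), attr(x, "n_obs")))
  df <- as.data.frame(x)
  df$signature <- sprintf("ddev_{%d,%d} = %.2f", df$delta_df, df$df_residual,
                          df$delta_dev)
  print(df, ...)
  invisible(x)
}

#' Remove zero cells before sensitivity refits
#'
#' Drops species-by-fruit cells whose larval survival is zero, whose egg
#' count is zero, or either, so the survival effect can be re-tested on the
#' cells where eggs were laid and/or larvae survived.
#'
#' @param cell_table data.frame with `eggs` and `survival` columns (see
#'   [cell_egg_table()]).
#' @param mode `"survival_zeros"`, `"oviposition_zeros"` or `"both"`.
#' @return the filtered table, with a `removed` attribute giving the number
#'   of dropped cells; an empty result is an error.
#' @export
zero_filter <- function(cell_table, mode = c("survival_zeros",
                                             "oviposition_zeros", "both")) {
  mode <- match.arg(mode)
  stopifnot(all(c("eggs", "survival") %in% names(cell_table)))
  drop <- switch(mode,
                 survival_zeros = cell_table$survival == 0,
                 oviposition_zeros = cell_table$eggs == 0,
                 both = cell_table$survival == 0 | cell_table$eggs == 0)
  out <- cell_table[!drop, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("zero filter removed every cell", call. = FALSE)
  attr(out, "removed") <- sum(drop)
  out
}

#' Cell-level observation table
#'
#' One row per species-by-fruit cell: total (or mean) no-choice egg count,
#' larval survival proportion, guild, and optionally the species' mean
#' preference alpha. Cells without survival trials are dropped (their
#' survival covariate does not exist); under the standard complete design
#' none are.
#'
#' @param dataset a `community_dataset`.
#' @param alpha optional named per-species alpha vector to attach.
#' @param response `"sum"` (default; an integer count, the Poisson response)
#'   or `"mean"` egg count per cell.
#' @return data.frame with columns `species`, `fruit`, `guild`, `eggs`,
#'   `survival` (+ `alpha`); `species` and `fruit` are factors in roster and
#'   catalogue order.
#' @export
cell_egg_table <- function(dataset, alpha = NULL, response = c("sum", "mean")) {
  response <- match.arg(response)
  E <- suppressWarnings(build_interaction_matrix(dataset, "eggs", response))
  S <- suppressWarnings(build_interaction_matrix(dataset, "survival"))
  long <- expand.grid(fruit = rownames(E), species = colnames(E),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$eggs <- E[cbind(long$fruit, long$species)]
  long$survival <- S[cbind(long$fruit, long$species)]
  long <- long[!is.na(long$survival), , drop = FALSE]
  long$species <- factor(long$species, levels = dataset$roster$species)
  long$fruit <- factor(long$fruit,
                       levels = as.character(dataset$catalog$fruit_id))
  long$guild <- dataset$roster$guild[as.integer(long$species)]
  if (!is.null(alpha)) long$alpha <- unname(alpha[as.character(long$species)])
  rownames(long) <- NULL
  long[, c("species", "fruit", "guild", "eggs", "survival",
           if (!is.null(alpha)) "alpha")]
}

#' Replicate-level observation table
#'
#' One row per no-choice oviposition replicate, with fruit and species as
#' factors and, optionally, the species' mean preference alpha attached as a
#' continuous covariate (constant within species).
#'
#' @inheritParams cell_egg_table
#' @return data.frame with columns `species`, `fruit`, `guild`, `replicate`,
#'   `eggs` (+ `alpha`).
#' @export
replicate_egg_table <- function(dataset, alpha = NULL) {
  nc <- dataset$oviposition[dataset$oviposition$assay == "no_choice", , drop = FALSE]
  out <- data.frame(
    species = factor(nc$species, levels = dataset$roster$species),
    fruit = factor(as.character(nc$fruit_id),
                   levels = as.character(dataset$catalog$fruit_id)),
    replicate = nc$replicate, eggs = nc$eggs, stringsAsFactors = FALSE)
  out$guild <- dataset$roster$guild[as.integer(out$species)]
  if (!is.null(alpha)) out$alpha <- unname(alpha[as.character(out$species)])
  out
}

#' The full analysis-of-deviance model suite
#'
#' Runs the deviance models of the preference-performance analysis:
#' \describe{
#'   \item{preference_by_fruit_alpha}{replicate-level eggs ~ fruit + alpha +
#'     fruit:alpha — fruit effects on oviposition and their modulation by
#'     the degree of specialisation.}
#'   \item{guild_coupling}{cell-level eggs ~ survival + guild +
#'     survival:guild — does the preference-performance relationship differ
#'     between specialists and generalists?}
#'   \item{generalists_survival / specialists_survival}{within-guild
#'     cell-level eggs ~ survival.}
#'   \item{generalists_by_species / specialists_by_species}{within-guild
#'     eggs ~ survival + species + survival:species — species heterogeneity
#'     of the coupling.}
#'   \item{specialists_survival_no_zero_survival / _no_zero_eggs /
#'     _no_zero_both}{specialist eggs ~ survival refit after [zero_filter()]
#'     sensitivity removal.}
#' }
#'
#' @param dataset a `community_dataset`.
#' @param alpha_estimates an `alpha_distributions` object (or a named
#'   per-species numeric vector of preference alphas).
#' @param response cell-level egg response, `"sum"` or `"mean"`.
#' @param pvalue `"F"` or `"chisq"` (passed to [sequential_deviance()]).
#' @return named list of `deviance_table` objects.
#' @export
model_suite <- function(dataset, alpha_estimates, response = c("sum", "mean"),
                        pvalue = c("F", "chisq")) {
  response <- match.arg(response)
  pvalue <- match.arg(pvalue)
  alpha <- if (inherits(alpha_estimates, "alpha_distributions")) {
    s <- alpha_estimates$summary
    s <- s[s$measure == "eggs", , drop = FALSE]
    stats::setNames(s$mean_alpha, s$species)
  } else {
    stopifnot(is.numeric(alpha_estimates), !is.null(names(alpha_estimates)))
    alpha_estimates
  }
  rep_tab <- replicate_egg_table(dataset, alpha)
  cell_tab <- cell_egg_table(dataset, alpha, response)
  gen <- droplevels(cell_tab[cell_tab$guild == "generalist", , drop = FALSE])
  spc <- droplevels(cell_tab[cell_tab$guild == "specialist", , drop = FALSE])
  suite <- list(
    preference_by_fruit_alpha =
      sequential_deviance(c("fruit", "alpha", "fruit:alpha"), rep_tab,
                          "eggs", pvalue),
    guild_coupling =
      sequential_deviance(c("survival", "guild", "survival:guild"), cell_tab,
                          "eggs", pvalue),
    generalists_survival =
      sequential_deviance("survival", gen, "eggs", pvalue),
    specialists_survival =
      sequential_deviance("survival", spc, "eggs", pvalue),
    generalists_by_species =
      sequential_deviance(c("survival", "species", "survival:species"), gen,
                          "eggs", pvalue),
    specialists_by_species =
      sequential_deviance(c("survival", "species", "survival:species"), spc,
                          "eggs", pvalue)
  )
  for (mode in c("survival_zeros", "oviposition_zeros", "both")) {
    nm <- paste0("specialists_survival_no_zero_",
                 switch(mode, survival_zeros = "survival",
                        oviposition_zeros = "eggs", both = "both"))
    suite[[nm]] <- sequential_deviance("survival", zero_filter(spc, mode),
                                       "eggs", pvalue)
  }
  suite
}

#' Flatten a model suite into one tidy table
#'
#' @param suite named list of `deviance_table`s from [model_suite()].
#' @return data.frame with `model_id`, `term`, `delta_dev`, `delta_df`,
#'   `df_residual`, `F`, `p`, `dispersion`, `n_obs`.
#' @export
deviance_suite_table <- function(suite) {
  do.call(rbind, lapply(names(suite), function(id) {
    d <- as.data.frame(suite[[id]])
    d$model_id <- id
    d$dispersion <- attr(suite[[id]], "dispersion")
    d$n_obs <- attr(suite[[id]], "n_obs")
    d[, c("model_id", "term", "delta_dev", "delta_df", "df_residual",
          "F", "p", "dispersion", "n_obs")]
  }))
}
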