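#' Resampling plan for interaction-matrix bootstrap
#'
#' The scheme used to put a distribution on each species' alpha diversity:
#' build `n_matrices` interaction-matrix pairs by drawing, per
#' species-by-fruit cell, `k_oviposition` no-choice oviposition replicates
#' (egg value = sum of the drawn replicates, default a single replicate) and
#' `k_survival` survival cups (value = proportion pupating among the drawn
#' cups), sampling without replacement within a cell and independently
#' across cells and matrices.
#'
#' @param n_matrices number of resampled matrix pairs (default 1000).
#' @param k_oviposition oviposition replicates drawn per cell (default 1).
#' @param k_survival survival cups drawn per cell (default 5).
#' @param seed integer master seed; each matrix uses its own substream so
#'   enlarging `n_matrices` leaves earlier matrices unchanged.
#' @return object of class `resampling_plan`.
#' @export
resampling_plan <- function(n_matrices = 1000L, k_oviposition = 1L,
                            k_survival = 5L, seed = 1L) {
  stopifnot(n_matrices >= 1, k_oviposition >= 1, k_survival >= 1,
            length(seed) == 1L, is.finite(seed))
  structure(list(n_matrices = as.integer(n_matrices),
                 k_oviposition = as.integer(k_oviposition),
                 k_survival = as.integer(k_survival),
                 seed = as.integer(seed)),
            class = "resampling_plan")
}

# Per-cell replicate pools. Eggs: no-choice replicate counts per
# (fruit, species); survival: 0/1 cup outcomes.
cell_pools <- function(dataset) {
  fruits <- as.character(dataset$catalog$fruit_id)
  species <- dataset$roster$species
  nc <- dataset$oviposition[dataset$oviposition$assay == "no_choice", , drop = FALSE]
  eggs <- split(nc$eggs, list(factor(as.character(nc$fruit_id), levels = fruits),
                              factor(nc$species, levels = species)), sep = "\r")
  cups <- split(dataset$survival$pupated,
                list(factor(as.character(dataset$survival$fruit_id), levels = fruits),
                     factor(dataset$survival$species, levels = species)), sep = "\r")
  list(fruits = fruits, species = species, eggs = eggs, cups = cups)
}

#' Resample interaction-matrix pairs
#'
#' Draws the sequence of (eggs, survival) interaction matrices defined by a
#' [resampling_plan()]. Oviposition cells with no no-choice replicate raise
#' an error listing the cells; unobserved survival cells stay `NA`. Survival
#' cells with fewer cups than `k_survival` fall back to all available cups
#' (recorded in the `fallback_cells` attribute). If a species' drawn egg
#' column is all zero the column is redrawn (up to 100 times) so its diversity
#' stays defined; a species with no positive egg replicate anywhere keeps the
#' all-zero column.
#'
#' @param dataset a `community_dataset`.
#' @param plan a `resampling_plan`.
#' @return list of length `n_matrices`; each element is a list with numeric
#'   matrices `eggs` and `survival` (fruits by species). Deterministic given
#'   `(dataset, plan)`.
#' @export
resample_matrices <- function(dataset, plan) {
  stopifnot(inherits(dataset, "community_dataset"),
            inherits(plan, "resampling_plan"))
  pools <- cell_pools(dataset)
  nf <- length(pools$fruits); ns <- length(pools$species)
  n_eggs <- lengths(pools$eggs)
  if (any(n_eggs == 0L)) {
    empty <- names(pools$eggs)[n_eggs == 0L]
    stop(sprintf("no oviposition replicates for cell(s): %s",
                 paste(utils::head(gsub("\r", " x ", empty), 10L), collapse = "; ")),
         call. = FALSE)
  }
  if (any(n_eggs < plan$k_oviposition))
    stop("k_oviposition exceeds available replicates in some cells", call. = FALSE)
  n_cups <- lengths(pools$cups)
  k_surv <- pmin(n_cups, plan$k_survival)
  fallback <- gsub("\r", " x ", names(pools$cups)[n_cups > 0L & n_cups < plan$k_survival])
  # species that can never produce a positive egg column
  col_has_pos <- vapply(seq_len(ns), function(j) {
    any(unlist(pools$eggs[(j - 1L) * nf + seq_len(nf)]) > 0)
  }, logical(1))

  set.seed(plan$seed)
  substreams <- sample.int(.Machine$integer.max, plan$n_matrices)

  draw_egg_col <- function(j) {
    vapply(seq_len(nf), function(i) {
      pool <- pools$eggs[[(j - 1L) * nf + i]]
      if (plan$k_oviposition == 1L)
        pool[sample.int(length(pool), 1L)]
      else sum(pool[sample.int(length(pool), plan$k_oviposition)])
    }, numeric(1))
  }

  out <- vector("list", plan$n_matrices)
  for (m in seq_len(plan$n_matrices)) {
    set.seed(substreams[m])
    E <- matrix(0, nf, ns, dimnames = list(pools$fruits, pools$species))
    S <- matrix(NA_real_, nf, ns, dimnames = list(pools$fruits, pools$species))
    for (j in seq_len(ns)) {
      col <- draw_egg_col(j)
      if (col_has_pos[j]) {
        tries <- 0L
        while (all(col == 0) && tries < 100L) {
          col <- draw_egg_col(j)
          tries <- tries + 1L
        }
      }
      E[, j] <- col
      for (i in seq_len(nf)) {
        idx <- (j - 1L) * nf + i
        if (n_cups[idx] > 0L) {
          pool <- pools$cups[[idx]]
          k <- k_surv[idx]
          S[i, j] <- if (k == length(pool)) mean(pool)
                     else mean(pool[sample.int(length(pool), k)])
        }
      }
    }
    out[[m]] <- list(eggs = E, survival = S)
  }
  structure(out, fallback_cells = fallback, class = "resampled_matrices")
}

#' Resampling distributions of per-species alpha diversity
#'
#' Runs the matrix bootstrap and collects, for every species and for both
#' measures (no-choice eggs and larval survival), the Hill q = 1 diversity of
#' each resampled column, summarised by its mean and variance. A resample in
#' which a species' egg column is all zero despite redraws is recorded as
#' `NA` and excluded from the summary (counted in `n_dropped`).
#'
#' @param dataset a `community_dataset`.
#' @param plan a `resampling_plan`.
#' @return object of class `alpha_distributions`: list with `summary`
#'   (data.frame: `species`, `measure`, `mean_alpha`, `var_alpha`,
#'   `n_resamples`, `n_dropped`) and `samples` (data.frame: `matrix_index`,
#'   `species`, `measure`, `alpha`).
#' @export
alpha_distributions <- function(dataset, plan = resampling_plan()) {
  mats <- resample_matrices(dataset, plan)
  species <- dataset$roster$species
  B <- length(mats)
  one_measure <- function(get) {
    vapply(mats, function(m) {
      M <- get(m)
      vapply(species, function(sp) {
        w <- M[, sp]
        w <- w[!is.na(w)]
        if (length(w) == 0L || sum(w) <= 0) NA_real_ else hill_diversity(w, 1)
      }, numeric(1))
    }, numeric(length(species)))
  }
  a_eggs <- one_measure(function(m) m$eggs)        # species x B
  a_surv <- one_measure(function(m) m$survival)
  if (length(species) == 1L) {
    a_eggs <- matrix(a_eggs, nrow = 1L, dimnames = list(species))
    a_surv <- matrix(a_surv, nrow = 1L, dimnames = list(species))
  }
  summarise <- function(A, measure) {
    data.frame(species = species, measure = measure,
               mean_alpha = apply(A, 1, mean, na.rm = TRUE),
               var_alpha = apply(A, 1, stats::var, na.rm = TRUE),
               n_resamples = apply(A, 1, function(z) sum(!is.na(z))),
               n_dropped = apply(A, 1, function(z) sum(is.na(z))),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  long <- function(A, measure) {
    data.frame(matrix_index = rep(seq_len(B), each = length(species)),
               species = rep(species, B), measure = measure,
               alpha = as.vector(A), stringsAsFactors = FALSE)
  }
  structure(list(
    summary = rbind(summarise(a_eggs, "eggs"), summarise(a_surv, "survival")),
    samples = rbind(long(a_eggs, "eggs"), long(a_surv, "survival")),
    plan = plan
  ), class = "alpha_distributions")
}

#' @export
print.alpha_distributions <- function(x, ...) {
  cat(sprintf("alpha_distributions over %d resampled matrices\n",
              x$plan$n_matrices))
  print(x$summary, ...)
  invisible(x)
}

#' Classify species into specialists and generalists from alpha diversity
#'
#' Orders species by their mean preference alpha (effective host number from
#' no-choice eggs) and splits at the largest gap: the low set is labelled
#' specialist, the high set generalist. The separation score is the fraction
#' of paired resamples in which every generalist's alpha exceeds every
#' specialist's alpha. This classification is a diagnostic check of the
#' a-priori guilds, which remain the grouping factor for the deviance models.
#'
#' @param estimates an `alpha_distributions` object.
#' @param roster fly roster carrying the a-priori guilds.
#' @return data.frame (class `guild_assignment`): `species`,
#'   `a_priori_guild`, `assigned_guild`, `mean_alpha`, `separation_score`,
#'   `agrees`; attribute `degenerate` is `TRUE` when all means tie and the
#'   gap split is arbitrary.
#' @export
classify_by_alpha <- function(estimates, roster) {
  stopifnot(inherits(estimates, "alpha_distributions"))
  pref <- estimates$summary[estimates$summary$measure == "eggs", , drop = FALSE]
  if (nrow(pref) < 2L)
    stop("classification needs at least two species", call. = FALSE)
  ord <- order(pref$mean_alpha)
  means <- pref$mean_alpha[ord]
  gaps <- diff(means)
  degenerate <- max(gaps) <= 0
  cut <- if (degenerate) 1L else which.max(gaps)
  assigned <- rep("generalist", nrow(pref))
  assigned[ord[seq_len(cut)]] <- "specialist"

  samp <- estimates$samples[estimates$samples$measure == "eggs", , drop = FALSE]
  spec_sp <- pref$species[assigned == "specialist"]
  gen_sp <- pref$species[assigned == "generalist"]
  by_mat <- split(samp, samp$matrix_index)
  sep <- vapply(by_mat, function(d) {
    a <- d$alpha[match(spec_sp, d$species)]
    b <- d$alpha[match(gen_sp, d$species)]
    if (anyNA(a) || anyNA(b) || !length(a) || !length(b)) NA
    else min(b) > max(a)
  }, logical(1))
  score <- mean(sep, na.rm = TRUE)

  out <- data.frame(species = pref$species,
                    a_priori_guild = as.character(roster$guild[match(pref$species, roster$species)]),
                    assigned_guild = assigned,
                    mean_alpha = pref$mean_alpha,
                    separation_score = score,
                    stringsAsFactors = FALSE)
  out$agrees <- out$a_priori_guild == out$assigned_guild
  structure(out, degenerate = degenerate, class = c("guild_assignment", "data.frame"))
}
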