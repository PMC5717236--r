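#' Configuration of the synthetic community generator
#'
#' Defines a fruit-fly community with known diet breadth and known
#' preference-performance coupling, mirroring the standard assay design:
#' 29 catalogued fruits, two cucurbit specialists and four generalists, six
#' no-choice oviposition replicates per cell, twelve choice replicates on the
#' eight-fruit subset, and 30-50 single-larva survival cups per cell.
#'
#' Species i's preference is a Dirichlet host-weight vector `w_i`
#' (specialists concentrate mass on the specialist family block, generalists
#' are diffuse). A no-choice replicate on fruit j yields an overdispersed
#' count with mean `egg_scale * w_ij` (gamma-mixed Poisson with
#' `Var = phi * mean`); `egg_scale` is therefore the notional full-profile
#' egg load, calibrated so a top-ranked host (`w ~ 0.2-0.35`) receives the
#' 24-h output of five gravid females at peak fecundity. Survival follows
#' `logit(s_ij) = a_g + b_g * z_ij + eps`, with `z_ij` the within-species
#' standardised log-preference, so the coupling slope `b_g` is comparable
#' across species of different breadths; `b = 0` makes preference and
#' performance unrelated by construction.
#'
#' @param n_fruits number of fruits; 29 uses the embedded catalogue, other
#'   values build a synthetic catalogue with one specialist family block.
#' @param n_specialists,n_generalists guild sizes (defaults 2 and 4; the six
#'   community species names are used when sizes match the roster).
#' @param specialist_block family whose fruits carry the specialists' mass.
#' @param dirichlet_specialist_in,dirichlet_specialist_out,dirichlet_generalist
#'   Dirichlet concentrations (specialist in-block / out-of-block;
#'   generalist everywhere).
#' @param egg_scale expected full-profile egg total per no-choice replicate.
#' @param choice_scale expected cage-wide egg total per choice replicate;
#'   default `0.4 * egg_scale` (ten females sharing one cage for 24 h).
#' @param overdispersion_phi target quasi-Poisson dispersion (>= 1; 1 gives
#'   exact Poisson counts).
#' @param coupling_b,survival_intercept_a named per-guild coupling slopes
#'   and intercepts on the logit-survival scale.
#' @param noise_sd SD of the logit-survival noise.
#' @param n_nochoice_reps,n_choice_reps,choice_subset_size,survival_cups_range
#'   assay design constants.
#' @param n_females_nochoice,n_females_choice females per replicate.
#' @param replicate_override optional data.frame (`species`, `fruit_id`,
#'   `n_reps`) overriding the no-choice replicate count of specific cells.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return object of class `community_config` (a validated list).
#' @export
community_config <- function(n_fruits = 29L,
                             n_specialists = 2L, n_generalists = 4L,
                             specialist_block = "Cucurbitaceae",
                             dirichlet_specialist_in = 2,
                             dirichlet_specialist_out = 0.05,
                             dirichlet_generalist = 0.5,
                             egg_scale = 900,
                             choice_scale = NULL,
                             overdispersion_phi = 3,
                             coupling_b = c(specialist = 2.5, generalist = 0),
                             survival_intercept_a = c(specialist = -2, generalist = 0),
                             noise_sd = 0.5,
                             n_nochoice_reps = 6L, n_choice_reps = 12L,
                             choice_subset_size = 8L,
                             survival_cups_range = c(30L, 50L),
                             n_females_nochoice = 5L, n_females_choice = 10L,
                             replicate_override = NULL,
                             seed = 1L) {
  if (is.null(choice_scale)) choice_scale <- 0.4 * egg_scale
  cfg <- list(n_fruits = as.integer(n_fruits),
              n_specialists = as.integer(n_specialists),
              n_generalists = as.integer(n_generalists),
              specialist_block = specialist_block,
              dirichlet_specialist_in = dirichlet_specialist_in,
              dirichlet_specialist_out = dirichlet_specialist_out,
              dirichlet_generalist = dirichlet_generalist,
              egg_scale = egg_scale, choice_scale = choice_scale,
              overdispersion_phi = overdispersion_phi,
              coupling_b = coupling_b,
              survival_intercept_a = survival_intercept_a,
              noise_sd = noise_sd,
              n_nochoice_reps = as.integer(n_nochoice_reps),
              n_choice_reps = as.integer(n_choice_reps),
              choice_subset_size = as.integer(choice_subset_size),
              survival_cups_range = as.integer(survival_cups_range),
              n_females_nochoice = as.integer(n_females_nochoice),
              n_females_choice = as.integer(n_females_choice),
              replicate_override = replicate_override,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_fruits >= 2, n_specialists >= 0, n_generalists >= 0,
              n_specialists + n_generalists >= 1,
              dirichlet_specialist_in > 0, dirichlet_specialist_out > 0,
              dirichlet_generalist > 0,
              egg_scale > 0, choice_scale > 0, overdispersion_phi >= 1,
              all(c("specialist", "generalist") %in% names(coupling_b)),
              all(c("specialist", "generalist") %in% names(survival_intercept_a)),
              noise_sd >= 0, n_nochoice_reps >= 1, n_choice_reps >= 1,
              choice_subset_size >= 2, choice_subset_size <= n_fruits,
              length(survival_cups_range) == 2,
              survival_cups_range[1] >= 1,
              survival_cups_range[2] >= survival_cups_range[1],
              n_females_nochoice >= 1, n_females_choice >= 1,
              length(seed) == 1, is.finite(seed))
  })
  if (!is.null(replicate_override))
    stopifnot(is.data.frame(replicate_override),
              all(c("species", "fruit_id", "n_reps") %in% names(replicate_override)),
              all(replicate_override$n_reps >= 1))
  structure(cfg, class = "community_config")
}

config_catalog <- function(cfg) {
  if (cfg$n_fruits == 29L) return(host_catalog())
  # generic stand-in catalogue: one 6-fruit specialist block, rest singleton
  # families; the first choice_subset_size fruits form the choice subset
  block <- min(6L, cfg$n_fruits)
  fam <- c(rep(cfg$specialist_block, block),
           paste0("Family_", seq_len(cfg$n_fruits - block)))
  data.frame(fruit_id = seq_len(cfg$n_fruits), family = fam,
             scientific_name = paste0("Hostus syntheticus ", seq_len(cfg$n_fruits)),
             common_name = paste0("fruit_", seq_len(cfg$n_fruits)),
             in_choice_subset = seq_len(cfg$n_fruits) <= cfg$choice_subset_size,
             stringsAsFactors = FALSE)
}

config_roster <- function(cfg) {
  std <- fly_roster()
  if (cfg$n_specialists == 2L && cfg$n_generalists == 4L) return(std)
  data.frame(
    species = c(paste0("specialist_", seq_len(cfg$n_specialists)),
                paste0("generalist_", seq_len(cfg$n_generalists))),
    guild = factor(rep(c("specialist", "generalist"),
                       c(cfg$n_specialists, cfg$n_generalists)),
                   levels = c("specialist", "generalist")),
    stringsAsFactors = FALSE)
}

rdirichlet1 <- function(shape) {
  g <- pmax(stats::rgamma(length(shape), shape = shape, rate = 1), 1e-300)
  g / sum(g)
}

# gamma-mixed Poisson with Var = phi * mean (negative binomial,
# size = mu / (phi - 1)); phi = 1 collapses to Poisson
regg <- function(n, mu, phi) {
  mu <- rep_len(mu, n)
  out <- integer(n)
  tiny <- mu < 1e-12
  if (phi <= 1 + 1e-12) {
    out[!tiny] <- stats::rpois(sum(!tiny), mu[!tiny])
  } else {
    out[!tiny] <- stats::rnbinom(sum(!tiny), size = mu[!tiny] / (phi - 1),
                                 mu = mu[!tiny])
  }
  out
}

#' Generate a synthetic community with known truth
#'
#' Draws a complete replicate-level dataset (no-choice and choice
#' oviposition, per-cup survival) from a [community_config()], together with
#' the generating truth: each species' preference simplex `w`, its
#' host-specific survival probabilities `s`, and its true diet breadth
#' `exp(H(w))`.
#'
#' @param config a `community_config`.
#' @return list with elements `dataset` (a validated `community_dataset`)
#'   and `truth` (class `synthetic_truth`: matrices `w` and `s` of dimension
#'   species by fruits, `true_alpha`, `guild`, and the `config`).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  catalog <- config_catalog(config)
  roster <- config_roster(config)
  ns <- nrow(roster); nf <- nrow(catalog)
  in_block <- catalog$family == config$specialist_block
  if (!any(in_block) && config$n_specialists > 0)
    stop(sprintf("specialist block family '%s' not in catalogue",
                 config$specialist_block), call. = FALSE)
  set.seed(config$seed)

  w <- matrix(NA_real_, ns, nf, dimnames = list(roster$species, catalog$fruit_id))
  s <- matrix(NA_real_, ns, nf, dimnames = list(roster$species, catalog$fruit_id))
  for (i in seq_len(ns)) {
    g <- as.character(roster$guild[i])
    shape <- if (g == "specialist")
      ifelse(in_block, config$dirichlet_specialist_in,
             config$dirichlet_specialist_out)
    else rep(config$dirichlet_generalist, nf)
    w[i, ] <- rdirichlet1(shape)
    lw <- log(w[i, ])
    z <- (lw - mean(lw)) / stats::sd(lw)
    eta <- config$survival_intercept_a[[g]] + config$coupling_b[[g]] * z +
      stats::rnorm(nf, 0, config$noise_sd)
    s[i, ] <- stats::plogis(eta)
  }

  reps_for <- function(sp, fid) {
    ov <- config$replicate_override
    if (!is.null(ov)) {
      hit <- ov$species == sp & ov$fruit_id == fid
      if (any(hit)) return(as.integer(ov$n_reps[which(hit)[1]]))
    }
    config$n_nochoice_reps
  }

  ov_list <- vector("list", ns * nf)
  k <- 0L
  for (i in seq_len(ns)) for (j in seq_len(nf)) {
    nr <- reps_for(roster$species[i], catalog$fruit_id[j])
    k <- k + 1L
    ov_list[[k]] <- data.frame(
      species = roster$species[i], fruit_id = catalog$fruit_id[j],
      assay = "no_choice", replicate = seq_len(nr),
      n_females = config$n_females_nochoice,
      eggs = regg(nr, config$egg_scale * w[i, j], config$overdispersion_phi),
      stringsAsFactors = FALSE)
  }
  subset_idx <- which(catalog$in_choice_subset)
  ch_list <- vector("list", ns)
  for (i in seq_len(ns)) {
    wsub <- w[i, subset_idx] / sum(w[i, subset_idx])
    mu <- config$choice_scale * wsub
    ch_list[[i]] <- data.frame(
      species = roster$species[i],
      fruit_id = rep(catalog$fruit_id[subset_idx], config$n_choice_reps),
      assay = "choice",
      replicate = rep(seq_len(config$n_choice_reps), each = length(subset_idx)),
      n_females = config$n_females_choice,
      eggs = regg(length(subset_idx) * config$n_choice_reps, rep(mu, config$n_choice_reps),
                  config$overdispersion_phi),
      stringsAsFactors = FALSE)
  }
  sv_list <- vector("list", ns * nf)
  k <- 0L
  for (i in seq_len(ns)) for (j in seq_len(nf)) {
    ncup <- if (config$survival_cups_range[1] == config$survival_cups_range[2])
      config$survival_cups_range[1]
    else sample(seq(config$survival_cups_range[1],
                    config$survival_cups_range[2]), 1L)
    k <- k + 1L
    sv_list[[k]] <- data.frame(
      species = roster$species[i], fruit_id = catalog$fruit_id[j],
      cup = seq_len(ncup),
      pupated = stats::rbinom(ncup, 1L, s[i, j]),
      stringsAsFactors = FALSE)
  }

  dataset <- community_dataset(
    catalog, roster,
    oviposition = do.call(rbind, c(ov_list, ch_list)),
    survival = do.call(rbind, sv_list),
    cups_range = config$survival_cups_range)
  truth <- structure(list(
    w = w, s = s,
    true_alpha = apply(w, 1, function(p) hill_diversity(p, 1)),
    guild = stats::setNames(as.character(roster$guild), roster$species),
    config = config), class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}

#' True diet breadth of a synthetic community
#'
#' The effective number of hosts of each species' generating preference
#' simplex, `exp(H(w_i))` — the ground truth that estimated preference
#' alphas should recover.
#'
#' @param truth a `synthetic_truth`.
#' @return named numeric vector of effective host numbers.
#' @export
true_alpha <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  truth$true_alpha
}

#' Write the generating truth as a tidy table
#'
#' @param truth a `synthetic_truth`.
#' @param path output TSV path.
#' @return the path, invisibly. Columns: `species`, `fruit_id`, `w`, `s`,
#'   `true_alpha`, `guild`.
#' @export
write_truth_table <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  long <- expand.grid(species = rownames(truth$w),
                      fruit_id = as.integer(colnames(truth$w)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$w <- truth$w[cbind(long$species, as.character(long$fruit_id))]
  long$s <- truth$s[cbind(long$species, as.character(long$fruit_id))]
  long$true_alpha <- truth$true_alpha[long$species]
  long$guild <- truth$guild[long$species]
  write_tidy_table(long, path)
}
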