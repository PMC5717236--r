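# Small hand-built community: 3 fruits, 2 species, complete design,
# deterministic values. Fruit 1 is the specialist's host.
tiny_catalog <- function() {
  data.frame(fruit_id = 1:3,
             family = c("Cucurbitaceae", "Myrtaceae", "Solanaceae"),
             scientific_name = paste("Plantus", c("unus", "duo", "tres")),
             common_name = c("gourd", "berry", "nightshade"),
             in_choice_subset = c(TRUE, TRUE, FALSE),
             stringsAsFactors = FALSE)
}

tiny_roster <- function() {
  data.frame(species = c("spec_a", "gen_b"),
             guild = factor(c("specialist", "generalist"),
                            levels = c("specialist", "generalist")),
             stringsAsFactors = FALSE)
}

tiny_dataset <- function(eggs = NULL, pupated = NULL) {
  grid <- expand.grid(species = c("spec_a", "gen_b"), fruit_id = 1:3,
                      replicate = 1:2, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$species, grid$fruit_id, grid$replicate), ]
  if (is.null(eggs)) {
    # spec_a: all eggs on fruit 1; gen_b: even spread
    base <- ifelse(grid$species == "spec_a",
                   ifelse(grid$fruit_id == 1, 30, 0), 10)
    eggs <- base + grid$replicate - 1L   # replicates differ by 1 egg
  } else if (is.function(eggs)) {
    eggs <- mapply(eggs, grid$species, grid$fruit_id, grid$replicate)
  }
  ovi <- data.frame(grid[c("species", "fruit_id")], assay = "no_choice",
                    replicate = grid$replicate, n_females = 5L,
                    eggs = as.integer(eggs), stringsAsFactors = FALSE)
  cup_grid <- expand.grid(species = c("spec_a", "gen_b"), fruit_id = 1:3,
                          cup = 1:5, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
  cup_grid <- cup_grid[order(cup_grid$species, cup_grid$fruit_id, cup_grid$cup), ]
  if (is.null(pupated)) {
    pupated <- ifelse(cup_grid$species == "spec_a",
                      as.integer(cup_grid$fruit_id == 1),
                      as.integer(cup_grid$cup <= 3))
  }
  surv <- data.frame(cup_grid, pupated = as.integer(pupated),
                     stringsAsFactors = FALSE)
  rownames(ovi) <- NULL
  rownames(surv) <- NULL
  community_dataset(tiny_catalog(), tiny_roster(), ovi, surv,
                    cups_range = c(5L, 5L))
}

# One default synthetic community, generated once per test run.
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_community(community_config(seed = 101L))
    cache
  }
})

# Pair of vectors with an exact sample correlation r (Gram-Schmidt).
pair_with_correlation <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(lm(e ~ x))
  xs <- scale(x)[, 1]
  es <- scale(e)[, 1]
  list(x = xs, y = r * xs + sqrt(1 - r^2) * es)
}
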