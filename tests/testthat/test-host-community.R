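test_that("embedded host catalogue matches the community design", {
  cat29 <- host_catalog()
  expect_equal(nrow(cat29), 29L)
  expect_equal(cat29$fruit_id, 1:29)
  expect_equal(length(unique(cat29$family)), 15L)
  expect_equal(sum(cat29$in_choice_subset), 8L)
  expect_setequal(cat29$common_name[cat29$in_choice_subset],
                  c("Mango", "Indian almond", "Melon", "Pumpkin",
                    "Strawberry guava", "Guava", "Chili", "Tomato"))
  expect_equal(sum(cat29$family == "Cucurbitaceae"), 6L)

  roster <- fly_roster()
  expect_equal(nrow(roster), 6L)
  expect_equal(as.vector(table(roster$guild)), c(2L, 4L))
})

test_that("community_dataset validates structure and reports missing cells", {
  d <- tiny_dataset()
  expect_s3_class(d, "community_dataset")
  v <- attr(d, "validation")
  expect_length(v$missing_egg_cells, 0L)
  expect_length(v$missing_survival_cells, 0L)

  bad <- d$oviposition
  bad$eggs[3] <- -1L
  expect_error(community_dataset(d$catalog, d$roster, bad, d$survival),
               "non-negative")
  bad <- d$oviposition
  bad$species[1] <- "nobody"
  expect_error(community_dataset(d$catalog, d$roster, bad, d$survival),
               "unknown species")
  bad <- d$oviposition
  bad$replicate[2] <- bad$replicate[1]
  expect_error(community_dataset(d$catalog, d$roster, bad, d$survival),
               "duplicate")
  bad <- d$survival
  bad$pupated[1] <- 2L
  expect_error(community_dataset(d$catalog, d$roster, d$oviposition, bad),
               "0 or 1")

  # dropping a cell's records is reported, not fatal
  ovi <- d$oviposition[!(d$oviposition$species == "gen_b" & d$oviposition$fruit_id == 3), ]
  d2 <- community_dataset(d$catalog, d$roster, ovi, d$survival)
  expect_match(attr(d2, "validation")$missing_egg_cells, "gen_b 3", all = FALSE)
})

test_that("tidy tables round-trip through write and read unchanged", {
  d <- tiny_dataset()
  dir <- withr::local_tempdir()
  write_community(d, dir)
  d2 <- read_community(dir)
  expect_equal(d2$oviposition, d$oviposition)
  expect_equal(d2$survival, d$survival)
  expect_equal(d2$catalog, d$catalog)
  expect_equal(as.character(d2$roster$guild), as.character(d$roster$guild))

  # empty table with header reads to an empty list of records
  empty <- file.path(dir, "empty.tsv")
  writeLines("species\tfruit_id\tassay\treplicate\tn_females\teggs", empty)
  expect_equal(nrow(read_oviposition_table(empty)), 0L)

  # malformed rows are named by file line
  badfile <- file.path(dir, "bad.tsv")
  writeLines(c("species\tfruit_id\tassay\treplicate\tn_females\teggs",
               "spec_a\t1\tno_choice\t1\t5\t-1"), badfile)
  expect_error(read_oviposition_table(badfile), "line\\(s\\) 2")
})

test_that("survival aggregation gives per-cell pupation proportions", {
  trials <- data.frame(species = "s", fruit_id = 1L, cup = 1:50,
                       pupated = c(rep(1L, 13), rep(0L, 37)))
  cell <- aggregate_survival(trials)
  expect_equal(cell$n_trials, 50L)
  expect_equal(cell$n_pupae, 13L)
  expect_equal(cell$survival, 0.26)

  zero <- aggregate_survival(transform(trials, pupated = 0L))
  expect_equal(zero$survival, 0)
  all1 <- aggregate_survival(transform(trials[1:40, ], pupated = 1L))
  expect_equal(all1$survival, 1)
  # unobserved cells are simply absent
  expect_equal(nrow(aggregate_survival(trials[0, ])), 0L)
})

test_that("interaction matrices span the full catalogue-by-roster design", {
  sim <- default_sim()
  E <- build_interaction_matrix(sim$dataset, "eggs", "sum")
  expect_equal(dim(E), c(29L, 6L))
  expect_true(all(E >= 0))
  S <- build_interaction_matrix(sim$dataset, "survival")
  expect_equal(dim(S), c(29L, 6L))
  expect_true(all(S >= 0 & S <= 1))

  d <- tiny_dataset()
  # sum over k replicates equals k times the mean when every cell has k
  Esum <- build_interaction_matrix(d, "eggs", "sum")
  Emean <- build_interaction_matrix(d, "eggs", "mean")
  expect_equal(Esum, 2 * Emean)

  # single-record dataset: one nonzero cell, unobserved cells 0 with warning
  one <- d$oviposition[d$oviposition$species == "spec_a" &
                         d$oviposition$fruit_id == 1 &
                         d$oviposition$replicate == 1, ]
  one$eggs <- 7L
  expect_warning(
    E1 <- build_interaction_matrix(
      community_dataset(d$catalog, d$roster, one, d$survival), "eggs"),
    "unobserved")
  expect_equal(sum(E1), 7)
  expect_equal(E1["1", "spec_a"], 7)

  # choice records never enter the preference matrix
  extra <- rbind(d$oviposition,
                 data.frame(species = "spec_a", fruit_id = 2L, assay = "choice",
                            replicate = 1L, n_females = 10L, eggs = 500L))
  d3 <- community_dataset(d$catalog, d$roster, extra, d$survival)
  expect_equal(build_interaction_matrix(d3, "eggs", "sum"), Esum)

  # survival: unobserved cells are NA, not zero
  surv <- d$survival[d$survival$fruit_id != 3, ]
  d4 <- community_dataset(d$catalog, d$roster, d$oviposition, surv)
  S4 <- build_interaction_matrix(d4, "survival")
  expect_true(all(is.na(S4["3", ])))
})
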