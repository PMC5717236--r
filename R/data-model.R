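#' Assemble and validate a community dataset
#'
#' Bundles the host catalogue, the fly roster, replicate-level oviposition
#' records and per-cup larval survival trials into a single validated object.
#' Structural violations (unknown fruits or species, negative egg counts,
#' duplicate replicate keys, non-binary pupation outcomes) are errors;
#' design-completeness issues (unobserved species-by-fruit cells, cup counts
#' outside the declared range) are enumerated in the attached validation
#' report rather than failing silently.
#'
#' @param catalog host catalogue as returned by [host_catalog()].
#' @param roster fly roster as returned by [fly_roster()]; column `guild`
#'   must contain both levels for guild-contrast models.
#' @param oviposition data.frame with columns `species`, `fruit_id`, `assay`
#'   (`"no_choice"` or `"choice"`), `replicate`, `n_females`, `eggs`.
#' @param survival data.frame with columns `species`, `fruit_id`, `cup`,
#'   `pupated` (0/1, one neonate larva per cup).
#' @param cups_range declared per-cell replication range for survival trials;
#'   cells outside it are logged in the report, not rejected.
#'
#' @return An object of class `community_dataset`: a list with elements
#'   `catalog`, `roster`, `oviposition`, `survival` and a `validation`
#'   attribute (list of character vectors `missing_egg_cells`,
#'   `missing_survival_cells`, `cup_range_notes`).
#' @export
community_dataset <- function(catalog, roster, oviposition, survival,
                              cups_range = c(30L, 50L)) {
  stopifnot(is.data.frame(catalog), is.data.frame(roster),
            is.data.frame(oviposition), is.data.frame(survival))
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s table is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  need(catalog, c("fruit_id", "family", "scientific_name", "in_choice_subset"), "catalog")
  need(roster, c("species", "guild"), "roster")
  need(oviposition, c("species", "fruit_id", "assay", "replicate", "n_females", "eggs"), "oviposition")
  need(survival, c("species", "fruit_id", "cup", "pupated"), "survival")

  if (anyDuplicated(catalog$fruit_id))
    stop("catalog fruit_id values must be unique", call. = FALSE)
  if (!identical(sort(as.integer(catalog$fruit_id)), seq_len(nrow(catalog))))
    stop("catalog fruit_id values must be contiguous from 1", call. = FALSE)
  if (anyDuplicated(roster$species))
    stop("roster species names must be unique", call. = FALSE)
  roster$guild <- factor(as.character(roster$guild),
                         levels = c("specialist", "generalist"))
  if (anyNA(roster$guild))
    stop("roster guild must be 'specialist' or 'generalist'", call. = FALSE)

  bad_row <- function(df, ok, msg) {
    if (any(!ok))
      stop(sprintf("%s (rows: %s)", msg,
                   paste(utils::head(which(!ok), 10L), collapse = ", ")),
           call. = FALSE)
  }
  bad_row(oviposition, oviposition$species %in% roster$species,
          "oviposition records reference unknown species")
  bad_row(oviposition, oviposition$fruit_id %in% catalog$fruit_id,
          "oviposition records reference uncatalogued fruits")
  bad_row(oviposition, oviposition$assay %in% c("no_choice", "choice"),
          "oviposition assay must be 'no_choice' or 'choice'")
  bad_row(oviposition, is.finite(oviposition$eggs) & oviposition$eggs >= 0 &
            oviposition$eggs == round(oviposition$eggs),
          "egg counts must be non-negative integers")
  key <- with(oviposition, paste(species, fruit_id, assay, replicate))
  bad_row(oviposition, !duplicated(key),
          "duplicate (species, fruit, assay, replicate) oviposition keys")

  bad_row(survival, survival$species %in% roster$species,
          "survival trials reference unknown species")
  bad_row(survival, survival$fruit_id %in% catalog$fruit_id,
          "survival trials reference uncatalogued fruits")
  bad_row(survival, survival$pupated %in% c(0, 1),
          "pupation outcomes must be 0 or 1 (one larva per cup)")

  # design-completeness report (informative, never fatal)
  cells <- expand.grid(species = roster$species, fruit_id = catalog$fruit_id,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ckey <- paste(cells$species, cells$fruit_id)
  nc <- oviposition[oviposition$assay == "no_choice", , drop = FALSE]
  missing_eggs <- ckey[!ckey %in% paste(nc$species, nc$fruit_id)]
  missing_surv <- ckey[!ckey %in% paste(survival$species, survival$fruit_id)]
  cups <- table(paste(survival$species, survival$fruit_id))
  off <- cups[cups < cups_range[1] | cups > cups_range[2]]
  cup_notes <- if (length(off))
    sprintf("%s: %d cups (declared range %d-%d)", names(off), as.integer(off),
            cups_range[1], cups_range[2]) else character(0)

  structure(
    list(catalog = catalog, roster = roster,
         oviposition = oviposition, survival = survival),
    validation = list(missing_egg_cells = missing_eggs,
                      missing_survival_cells = missing_surv,
                      cup_range_notes = cup_notes),
    class = "community_dataset"
  )
}

#' @export
print.community_dataset <- function(x, ...) {
  v <- attr(x, "validation")
  cat(sprintf("community_dataset: %d fruits, %d fly species\n",
              nrow(x$catalog), nrow(x$roster)))
  cat(sprintf("  oviposition records: %d (%d no-choice, %d choice)\n",
              nrow(x$oviposition), sum(x$oviposition$assay == "no_choice"),
              sum(x$oviposition$assay == "choice")))
  cat(sprintf("  survival cups: %d over %d cells\n", nrow(x$survival),
              length(unique(paste(x$survival$species, x$survival$fruit_id)))))
  if (length(v$missing_egg_cells))
    cat(sprintf("  unobserved egg cells: %d\n", length(v$missing_egg_cells)))
  if (length(v$missing_survival_cells))
    cat(sprintf("  unobserved survival cells: %d\n", length(v$missing_survival_cells)))
  if (length(v$cup_range_notes))
    cat(sprintf("  cells outside cup range: %d\n", length(v$cup_range_notes)))
  invisible(x)
}

read_typed_table <- function(path, coltypes, what) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(names(coltypes), names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s in '%s'", what,
                 paste(miss, collapse = ", "), path), call. = FALSE)
  for (col in names(coltypes)) {
    raw <- df[[col]]
    conv <- switch(coltypes[[col]],
                   integer = suppressWarnings(as.integer(raw)),
                   numeric = suppressWarnings(as.numeric(raw)),
                   character = as.character(raw))
    bad <- which(is.na(conv) & !is.na(raw))
    if (length(bad))
      stop(sprintf("%s: column '%s' not %s at file line(s) %s of '%s'",
                   what, col, coltypes[[col]],
                   paste(utils::head(bad + 1L, 10L), collapse = ", "), path),
           call. = FALSE)
    df[[col]] <- conv
  }
  df[names(coltypes)]
}

#' Read and write the tidy community tables
#'
#' Tab-delimited, UTF-8, one observation per row, mandatory header. The four
#' tables are `hosts.tsv` (the catalogue), `roster.tsv` (species, guild),
#' `oviposition.tsv` (replicate-level egg counts) and `survival.tsv`
#' (per-cup pupation outcomes). Malformed rows are reported with their file
#' line numbers; unknown fruits or species are caught when the tables are
#' assembled with [community_dataset()].
#'
#' @param path file to read from or write to.
#' @return `read_*` functions return a typed data.frame; negative egg counts
#'   or non-binary pupation outcomes raise an error naming the offending rows.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_oviposition_table <- function(path) {
  df <- read_typed_table(path, c(species = "character", fruit_id = "integer",
                                 assay = "character", replicate = "integer",
                                 n_females = "integer", eggs = "integer"),
                         "oviposition")
  bad <- which(df$eggs < 0)
  if (length(bad))
    stop(sprintf("oviposition: negative egg count at file line(s) %s",
                 paste(utils::head(bad + 1L, 10L), collapse = ", ")), call. = FALSE)
  df
}

#' @rdname table_io
#' @export
read_survival_table <- function(path) {
  df <- read_typed_table(path, c(species = "character", fruit_id = "integer",
                                 cup = "integer", pupated = "integer"),
                         "survival")
  bad <- which(!df$pupated %in% c(0L, 1L))
  if (length(bad))
    stop(sprintf("survival: pupated must be 0/1 at file line(s) %s",
                 paste(utils::head(bad + 1L, 10L), collapse = ", ")), call. = FALSE)
  df
}

#' @rdname table_io
#' @export
read_roster_table <- function(path) {
  df <- read_typed_table(path, c(species = "character", guild = "character"), "roster")
  df$guild <- factor(df$guild, levels = c("specialist", "generalist"))
  df
}

#' @rdname table_io
#' @export
read_host_table <- function(path) {
  df <- read_typed_table(path, c(fruit_id = "integer", family = "character",
                                 scientific_name = "character",
                                 common_name = "character",
                                 in_choice_subset = "integer"), "hosts")
  df$in_choice_subset <- df$in_choice_subset == 1L
  df
}

#' @rdname table_io
#' @param x data.frame (or, for [write_community()], a `community_dataset`).
#' @export
write_tidy_table <- function(x, path) {
  df <- as.data.frame(x)
  if ("in_choice_subset" %in% names(df))
    df$in_choice_subset <- as.integer(df$in_choice_subset)
  if ("guild" %in% names(df)) df$guild <- as.character(df$guild)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname table_io
#' @param dataset a `community_dataset`.
#' @param dir directory for the four tables (created if absent).
#' @export
write_community <- function(dataset, dir) {
  stopifnot(inherits(dataset, "community_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tidy_table(dataset$catalog, file.path(dir, "hosts.tsv"))
  write_tidy_table(dataset$roster, file.path(dir, "roster.tsv"))
  write_tidy_table(dataset$oviposition, file.path(dir, "oviposition.tsv"))
  write_tidy_table(dataset$survival, file.path(dir, "survival.tsv"))
  invisible(dir)
}

#' @rdname table_io
#' @export
read_community <- function(dir) {
  community_dataset(
    catalog = read_host_table(file.path(dir, "hosts.tsv")),
    roster = read_roster_table(file.path(dir, "roster.tsv")),
    oviposition = read_oviposition_table(file.path(dir, "oviposition.tsv")),
    survival = read_survival_table(file.path(dir, "survival.tsv"))
  )
}

#' Aggregate per-cup survival trials into cell-level proportions
#'
#' Larval performance for a species on a fruit is the proportion of cups
#' (one neonate larva each) from which a pupa was recovered.
#'
#' @param trials data.frame of survival trials (`species`, `fruit_id`, `cup`,
#'   `pupated`).
#' @return data.frame with one row per observed (species, fruit) cell:
#'   `species`, `fruit_id`, `n_trials`, `n_pupae`, `survival`. Cells with no
#'   trials are simply absent (zero trials is not zero survival).
#' @export
aggregate_survival <- function(trials) {
  stopifnot(all(c("species", "fruit_id", "pupated") %in% names(trials)))
  if (nrow(trials) == 0L)
    return(data.frame(species = character(0), fruit_id = integer(0),
                      n_trials = integer(0), n_pupae = integer(0),
                      survival = numeric(0)))
  agg <- stats::aggregate(pupated ~ species + fruit_id, data = trials,
                          FUN = function(z) c(n = length(z), k = sum(z)))
  out <- data.frame(species = agg$species, fruit_id = agg$fruit_id,
                    n_trials = as.integer(agg$pupated[, "n"]),
                    n_pupae = as.integer(agg$pupated[, "k"]),
                    stringsAsFactors = FALSE)
  out$survival <- out$n_pupae / out$n_trials
  out[order(out$species, out$fruit_id), , drop = FALSE]
}

#' Build the plants-by-species interaction matrix
#'
#' Collapses a community dataset into the full catalogue-by-roster matrix on
#' which host-use diversity is computed: 29 rows (plants) by 6 columns (fly
#' species) for the default community design. Oviposition preference uses
#' no-choice egg counts only; choice records never enter the matrix.
#'
#' @param dataset a `community_dataset`.
#' @param measure `"eggs"` (no-choice egg counts) or `"survival"`
#'   (proportion of cups pupating).
#' @param statistic for eggs, `"sum"` or `"mean"` over replicates; ignored
#'   for survival, which is always the pooled proportion.
#' @return numeric matrix with fruit ids as row names and species as column
#'   names, and a `measure` attribute. Unobserved egg cells are 0 (with a
#'   warning; the design is nominally complete); unobserved survival cells
#'   are `NA`.
#' @export
build_interaction_matrix <- function(dataset, measure = c("eggs", "survival"),
                                     statistic = c("sum", "mean")) {
  stopifnot(inherits(dataset, "community_dataset"))
  measure <- match.arg(measure)
  statistic <- match.arg(statistic)
  fruits <- dataset$catalog$fruit_id
  species <- dataset$roster$species
  m <- matrix(if (measure == "eggs") 0 else NA_real_,
              nrow = length(fruits), ncol = length(species),
              dimnames = list(as.character(fruits), species))
  if (measure == "eggs") {
    rec <- dataset$oviposition[dataset$oviposition$assay == "no_choice", , drop = FALSE]
    if (nrow(rec) == 0L) stop("no no-choice oviposition records", call. = FALSE)
    f <- if (statistic == "sum") sum else mean
    agg <- stats::aggregate(eggs ~ species + fruit_id, data = rec, FUN = f)
    m[cbind(as.character(agg$fruit_id), agg$species)] <- agg$eggs
    n_missing <- length(fruits) * length(species) - nrow(agg)
    if (n_missing > 0L)
      warning(sprintf("%d unobserved egg cell(s) set to 0", n_missing), call. = FALSE)
  } else {
    cells <- aggregate_survival(dataset$survival)
    if (nrow(cells) == 0L) stop("no survival trials", call. = FALSE)
    m[cbind(as.character(cells$fruit_id), cells$species)] <- cells$survival
  }
  attr(m, "measure") <- measure
  m
}
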