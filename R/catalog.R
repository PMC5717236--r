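#' Host-plant catalogue of the La Réunion fruit-fly community design
#'
#' The 29 fruit species (15 botanical families) used to assay oviposition
#' preference and larval performance, with the eight-fruit subset offered in
#' the choice experiment flagged. Fruit identifiers are contiguous from 1 and
#' stable across all package functions.
#'
#' @return A data.frame with columns `fruit_id` (integer), `family`,
#'   `scientific_name`, `common_name` (character) and `in_choice_subset`
#'   (logical), one row per fruit, ordered by `fruit_id`.
#' @examples
#' cat29 <- host_catalog()
#' nrow(cat29)                       # 29 fruits
#' length(unique(cat29$family))      # 15 families
#' sum(cat29$in_choice_subset)       # 8 fruits offered in the choice cage
#' @export
host_catalog <- function() {
  entries <- list(
    list(1L,  "Anacardiaceae", "Mangifera indica",                     "Mango",           TRUE),
    list(2L,  "Annonaceae",    "Annona reticulata",                    "Custard apple",   FALSE),
    list(3L,  "Cactaceae",     "Hylocereus undatus",                   "Dragon fruit",    FALSE),
    list(4L,  "Caricaceae",    "Carica papaya",                        "Papaya",          FALSE),
    list(5L,  "Combretaceae",  "Terminalia catappa",                   "Indian almond",   TRUE),
    list(6L,  "Cucurbitaceae", "Citrullus lanatus",                    "Watermelon",      FALSE),
    list(7L,  "Cucurbitaceae", "Cucumis melo",                         "Melon",           TRUE),
    list(8L,  "Cucurbitaceae", "Cucumis sativus",                      "Cucumber",        FALSE),
    list(9L,  "Cucurbitaceae", "Cucurbita maxima",                     "Pumpkin",         TRUE),
    list(10L, "Cucurbitaceae", "Cucurbita pepo",                       "Zucchini",        FALSE),
    list(11L, "Cucurbitaceae", "Sechium edule",                        "Chayote",         FALSE),
    list(12L, "Lauraceae",     "Persea americana",                     "Avocado",         FALSE),
    list(13L, "Lythraceae",    "Punica granatum",                      "Pomegranate",     FALSE),
    list(14L, "Moraceae",      "Ficus carica",                         "Fig",             FALSE),
    list(15L, "Myrtaceae",     "Psidium cattleyanum",                  "Strawberry guava", TRUE),
    list(16L, "Myrtaceae",     "Psidium guajava",                      "Guava",           TRUE),
    list(17L, "Myrtaceae",     "Syzygium jambos",                      "Rose apple",      FALSE),
    list(18L, "Myrtaceae",     "Syzygium samarangense",                "Java apple",      FALSE),
    list(19L, "Oxalidaceae",   "Averrhoa carambola",                   "Star fruit",      FALSE),
    list(20L, "Rosaceae",      "Eriobotrya japonica",                  "Loquat",          FALSE),
    list(21L, "Rosaceae",      "Prunus domestica",                     "Plum",            FALSE),
    list(22L, "Rosaceae",      "Prunus persica",                       "Peach",           FALSE),
    list(23L, "Rubiaceae",     "Coffea arabica",                       "Coffee",          FALSE),
    list(24L, "Rutaceae",      "Citrus reticulata x Citrus sinensis",  "Tangor",          FALSE),
    list(25L, "Solanaceae",    "Capsicum annuum",                      "Chili",           TRUE),
    list(26L, "Solanaceae",    "Solanum betaceum",                     "Tree tomato",     FALSE),
    list(27L, "Solanaceae",    "Solanum lycopersicum",                 "Tomato",          TRUE),
    list(28L, "Solanaceae",    "Solanum mauritianum",                  "Bugweed",         FALSE),
    list(29L, "Solanaceae",    "Solanum melongena",                    "Eggplant",        FALSE)
  )
  data.frame(
    fruit_id = vapply(entries, `[[`, integer(1), 1L),
    family = vapply(entries, `[[`, character(1), 2L),
    scientific_name = vapply(entries, `[[`, character(1), 3L),
    common_name = vapply(entries, `[[`, character(1), 4L),
    in_choice_subset = vapply(entries, `[[`, logical(1), 5L),
    stringsAsFactors = FALSE
  )
}

#' Fly-species roster with a-priori specialisation guilds
#'
#' The six tephritid species of the community, with guilds assigned a priori
#' from reported field host ranges: two cucurbit specialists and four
#' generalists. The a-priori guild is the grouping factor used in the
#' guild-contrast deviance models; the data-driven classification produced by
#' [classify_by_alpha()] is diagnostic, not a substitute.
#'
#' @return A data.frame with columns `species` (character) and `guild`
#'   (factor with levels `specialist`, `generalist`).
#' @export
fly_roster <- function() {
  data.frame(
    species = c("Dacus_demmerezi", "Zeugodacus_cucurbitae",
                "Ceratitis_catoirii", "Ceratitis_capitata",
                "Ceratitis_quilicii", "Bactrocera_zonata"),
    guild = factor(c("specialist", "specialist", "generalist", "generalist",
                     "generalist", "generalist"),
                   levels = c("specialist", "generalist")),
    stringsAsFactors = FALSE
  )
}
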