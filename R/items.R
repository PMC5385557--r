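#' Item tokens
#'
#' An item is the atomic unit of support counting: one indicator observed at
#' one level under one relation, e.g. `Apd == 1` (paraffin dirt present) or
#' `Nmob in[10,100) med` (methane-oxidizer count falling in an ordinal bin).
#' Items are represented as canonical strings so itemsets are plain character
#' vectors; two items are equal iff indicator, relation and level all match.
#'
#' @param indicator Indicator identifier (e.g. one of
#'   [microbial_indicators], or `"MP"` for the prospect outcome).
#' @param level Ordinal code or presence flag the raw value mapped to.
#' @param relation How the raw value maps to the token: one of
#'   `">="`, `"<="`, `">"`, `"<"`, `"=="`, or a bin predicate such as
#'   `"in[0,10)"`.
#' @return Character vector of canonical item tokens.
#' @examples
#' item("Apd", 1)
#' presence_item(c("Nmob", "Pheh"))
#' @export
item <- function(indicator, level = "1", relation = "==") {
  stopifnot(is.character(indicator) || is.factor(indicator))
  if (!length(indicator)) return(character())
  paste(as.character(indicator), relation, as.character(level))
}

#' @rdname item
#' @export
presence_item <- function(indicator) {
  item(indicator, level = "1", relation = "==")
}

#' Canonical itemset key
#'
#' Sorts item tokens in a locale-independent (radix) order, drops
#' duplicates, and joins them into a single stable string. The key is the
#' identity of an itemset throughout the package: support tables, rule keys
#' and serialized output all use it, so ordering inside a serialized itemset
#' is total and identical across runs and platforms.
#'
#' @param items Character vector of item tokens.
#' @return Length-1 character key (`""` for the empty itemset).
#' @examples
#' itemset_key(c("Pheh == 1", "Apd == 1"))
#' @export
itemset_key <- function(items) {
  paste(sort_items(items), collapse = " & ")
}

#' @rdname itemset_key
#' @export
sort_items <- function(items) {
  sort(unique(as.character(items)), method = "radix")
}

#' The 29 microbial prospection indicators
#'
#' Abbreviations for the soil microbial indicators of hydrocarbon seepage
#' mined by this package: counts of methane/ethane/propane/butane-oxidizing
#' bacteria, sulphate reducers, denitrifiers, dissolved/occluded/adsorbed
#' hydrocarbons, CO2 production rate, hydrogen sulphide, nitrogen species,
#' paraffin dirt, redox potential (Eh), pH, pH/Eh ratio, silica
#' precipitation, iron oxides, phosphates, carbonates, clays, and the
#' iron-mineral precipitates (pyrite, greigite, pyrrhotite, maghemite,
#' magnetic particles).
#'
#' @format Character vector of length 29.
#' @export
microbial_indicators <- c(
  "Nmob", "Neob", "Npob", "Nbob", "Nsrb", "Ndb", "Ni", "Nhdf", "Noh",
  "Nah", "Rcdp", "Nimb", "Ahs", "An", "Ano", "Apd", "Orp", "Phs", "Pheh",
  "Rps", "Aio", "Ap", "Ac", "Qc", "Ppr", "Pg", "Ppy", "Pmg", "Qmp"
)

#' Token for the prospect outcome
#'
#' The Boolean prospect outcome ("energy reserve found") enters mining as an
#' ordinary presence item with indicator id `MP` (microbial prospect).
#'
#' @return Length-1 character token.
#' @export
prospect_item <- function() presence_item("MP")
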