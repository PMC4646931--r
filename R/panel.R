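#' Default fatty acid panel
#'
#' A panel of 33 fatty acids commonly found in mammalian cells, spanning
#' 14:0 through 24:6, used for both the esterified acyl and the hydroxy
#' backbone moieties of the combinatorial FAHFA space. The exact published
#' panel is not reproduced in print, so this list is a documented
#' reconstruction of the common mammalian fatty acids in that range; every
#' library-size count depends only on the panel having 33 entries, and users
#' can substitute their own panel via [read_fa_panel()].
#'
#' Trivial abbreviations (PA, OA, LA, ...) feed FAHFA short names such as
#' "9-PAHSA" (PA esterified to hydroxy-SA at carbon 9).
#'
#' @return A tibble with columns `carbons`, `double_bonds`, `abbreviation`,
#'   `name` (33 rows).
#' @examples
#' default_fa_panel()
#' @export
default_fa_panel <- function() {
  tibble::tribble(
    ~carbons, ~double_bonds, ~abbreviation, ~name,
    14L, 0L, "MA",  "myristic acid",
    14L, 1L, NA,    "myristoleic acid",
    15L, 0L, NA,    "pentadecanoic acid",
    15L, 1L, NA,    "pentadecenoic acid",
    16L, 0L, "PA",  "palmitic acid",
    16L, 1L, "POA", "palmitoleic acid",
    17L, 0L, NA,    "margaric acid",
    17L, 1L, NA,    "heptadecenoic acid",
    18L, 0L, "SA",  "stearic acid",
    18L, 1L, "OA",  "oleic acid",
    18L, 2L, "LA",  "linoleic acid",
    18L, 3L, "ALA", "alpha-linolenic acid",
    18L, 4L, NA,    "stearidonic acid",
    19L, 0L, NA,    "nonadecanoic acid",
    20L, 0L, NA,    "arachidic acid",
    20L, 1L, NA,    "gondoic acid",
    20L, 2L, NA,    "eicosadienoic acid",
    20L, 3L, NA,    "dihomo-gamma-linolenic acid",
    20L, 4L, "AA",  "arachidonic acid",
    20L, 5L, "EPA", "eicosapentaenoic acid",
    21L, 0L, NA,    "heneicosanoic acid",
    22L, 0L, NA,    "behenic acid",
    22L, 1L, NA,    "erucic acid",
    22L, 2L, NA,    "docosadienoic acid",
    22L, 4L, NA,    "adrenic acid",
    22L, 5L, "DPA", "docosapentaenoic acid",
    22L, 6L, "DHA", "docosahexaenoic acid",
    23L, 0L, NA,    "tricosanoic acid",
    24L, 0L, NA,    "lignoceric acid",
    24L, 1L, NA,    "nervonic acid",
    24L, 4L, NA,    "tetracosatetraenoic acid",
    24L, 5L, NA,    "tetracosapentaenoic acid",
    24L, 6L, NA,    "tetracosahexaenoic acid"
  )
}

#' Read a fatty acid panel from a delimited file
#'
#' Expects a TSV or CSV with header columns `carbons`, `double_bonds`,
#' `abbreviation`, `name` (the last two may be empty). Rows must be unique
#' by (carbons, double_bonds); malformed integers and duplicates are errors
#' reported with their row number.
#'
#' @param path Path to the panel file.
#' @param delim Field delimiter; guessed from the file extension by default.
#' @return A panel tibble as from [default_fa_panel()].
#' @export
read_fa_panel <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    carbons = readr::col_character(),
    double_bonds = readr::col_character(),
    .default = readr::col_character()
  ), progress = FALSE)
  if (nrow(raw) == 0) rlang::abort("panel file is empty")
  required <- c("carbons", "double_bonds")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste("panel file lacks column(s):", paste(missing, collapse = ", ")))
  }
  carbons <- suppressWarnings(as.integer(raw$carbons))
  dbl <- suppressWarnings(as.integer(raw$double_bonds))
  bad <- which(is.na(carbons) | is.na(dbl) |
                 raw$carbons != as.character(carbons) |
                 raw$double_bonds != as.character(dbl))
  if (length(bad) > 0) {
    rlang::abort(paste0("malformed integer in panel row ", bad[1]))
  }
  dup <- which(duplicated(paste(carbons, dbl)))
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicate fatty acid in panel row ", dup[1],
                        " (", carbons[dup[1]], ":", dbl[dup[1]], ")"))
  }
  validate_chain(carbons, dbl)
  tibble::tibble(
    carbons = carbons,
    double_bonds = dbl,
    abbreviation = if ("abbreviation" %in% names(raw)) raw$abbreviation else NA_character_,
    name = if ("name" %in% names(raw)) raw$name else NA_character_
  )
}

#' Default saturated backbone lengths for the positional library
#'
#' Chain lengths of the saturated hydroxy fatty acid backbones used to
#' enumerate hydroxyl-positional structures. With the hydroxyl allowed on
#' every carbon except C1 (the carboxyl carbon) and the terminal carbon,
#' these eight lengths contribute \eqn{\sum (n-2) = 130} backbones, and
#' 130 x 33 acyl partners = 4290 positional structures. Like the panel,
#' the set is a documented reconstruction of the common saturated chains.
#'
#' @return Integer vector of backbone chain lengths.
#' @examples
#' sum(default_positional_lengths() - 2) # 130
#' @export
default_positional_lengths <- function() {
  c(14L, 15L, 16L, 17L, 18L, 20L, 22L, 24L)
}
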