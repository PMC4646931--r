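# FAHFA species are rows of a tibble: an esterified acyl chain, a hydroxy
# backbone, and (optionally) the backbone hydroxyl position. Naming follows
# the "16:0-(9-O-18:0)" shorthand; the short trivial form ("9-PAHSA") is
# derivable when both moieties carry panel abbreviations.

new_species <- function(acyl_carbons, acyl_db, backbone_carbons, backbone_db,
                        hydroxyl_position = NA_integer_,
                        abbreviation = NA_character_) {
  n <- length(acyl_carbons)
  hydroxyl_position <- vctrs::vec_recycle(as.integer(hydroxyl_position), n)
  bad <- !is.na(hydroxyl_position) &
    (hydroxyl_position < 2L | hydroxyl_position > backbone_carbons - 1L)
  if (any(bad)) {
    rlang::abort("hydroxyl position must lie in 2..(n-1) of the backbone chain")
  }
  if (any(!is.na(hydroxyl_position) & backbone_db > 0L)) {
    rlang::abort("positional structures require a saturated hydroxy backbone")
  }
  frm <- fahfa_formula(acyl_carbons, acyl_db, backbone_carbons, backbone_db)
  sp <- tibble::tibble(
    acyl_carbons = as.integer(acyl_carbons),
    acyl_db = as.integer(acyl_db),
    backbone_carbons = as.integer(backbone_carbons),
    backbone_db = as.integer(backbone_db),
    hydroxyl_position = hydroxyl_position,
    formula = formula_string(frm),
    neutral_mass = monoisotopic_mass(frm),
    precursor_mz = deprotonated_mz(frm),
    abbreviation = vctrs::vec_recycle(as.character(abbreviation), n)
  )
  sp$name <- species_name(sp)
  dplyr::relocate(sp, "name", "abbreviation")
}

#' Enumerate the general FAHFA structure space
#'
#' Every ordered (acyl, hydroxy backbone) pair drawn from a fatty acid
#' panel, with the hydroxyl position left unspecified: these are the
#' "general, semi-characterized" structures of the profiling library.
#' Enumeration order is deterministic (acyl-major, panel order), so the
#' 33-entry default panel always yields the same 1089 species in the same
#' order.
#'
#' @param panel A fatty acid panel tibble (see [default_fa_panel()]).
#' @return A species tibble with one row per structure: chain descriptors,
#'   `hydroxyl_position` (all `NA`), `formula`, `neutral_mass`,
#'   `precursor_mz` (\eqn{[M-H]^-}), `name` and `abbreviation`.
#' @examples
#' nrow(enumerate_general(default_fa_panel())) # 1089
#' @export
enumerate_general <- function(panel = default_fa_panel()) {
  if (nrow(panel) == 0) rlang::abort("panel must be non-empty")
  grid <- tidyr::expand_grid(
    acyl = seq_len(nrow(panel)),
    backbone = seq_len(nrow(panel))
  )
  abbr <- combine_abbreviation(
    panel$abbreviation[grid$acyl], panel$abbreviation[grid$backbone]
  )
  new_species(
    acyl_carbons = panel$carbons[grid$acyl],
    acyl_db = panel$double_bonds[grid$acyl],
    backbone_carbons = panel$carbons[grid$backbone],
    backbone_db = panel$double_bonds[grid$backbone],
    abbreviation = abbr
  )
}

#' Enumerate hydroxyl-positional FAHFA structures
#'
#' For each acyl chain in the panel and each saturated backbone length in
#' `lengths`, one structure per hydroxyl position p in 2..(n-1): the
#' hydroxyl may sit on any backbone carbon except the carboxyl carbon (C1)
#' and the terminal carbon. Unsaturated backbones are excluded (no
#' reference spectra exist to model them). The default configuration gives
#' 33 x 130 = 4290 structures.
#'
#' @inheritParams enumerate_general
#' @param lengths Integer vector of saturated backbone chain lengths.
#' @return A species tibble (see [enumerate_general()]) with
#'   `hydroxyl_position` set; order is acyl-major, then backbone length,
#'   then position.
#' @examples
#' nrow(enumerate_positional(default_fa_panel())) # 4290
#' @export
enumerate_positional <- function(panel = default_fa_panel(),
                                 lengths = default_positional_lengths()) {
  if (nrow(panel) == 0) rlang::abort("panel must be non-empty")
  if (any(lengths < 4)) rlang::abort("backbone lengths must be >= 4 carbons")
  backbones <- tidyr::expand_grid(n = as.integer(lengths)) |>
    dplyr::mutate(p = purrr::map(.data$n, ~seq(2L, .x - 1L))) |>
    tidyr::unnest("p")
  grid <- tidyr::expand_grid(acyl = seq_len(nrow(panel)),
                             bb = seq_len(nrow(backbones)))
  sat <- panel$abbreviation[match(paste(backbones$n[grid$bb], 0L),
                                  paste(panel$carbons, panel$double_bonds))]
  abbr <- combine_abbreviation(panel$abbreviation[grid$acyl], sat,
                               position = backbones$p[grid$bb])
  new_species(
    acyl_carbons = panel$carbons[grid$acyl],
    acyl_db = panel$double_bonds[grid$acyl],
    backbone_carbons = backbones$n[grid$bb],
    backbone_db = 0L,
    hydroxyl_position = backbones$p[grid$bb],
    abbreviation = abbr
  )
}

combine_abbreviation <- function(acyl_abbr, backbone_abbr, position = NA_integer_) {
  out <- ifelse(
    is.na(acyl_abbr) | is.na(backbone_abbr),
    NA_character_,
    paste0(acyl_abbr, "H", backbone_abbr)
  )
  ifelse(is.na(out) | is.na(position), out, paste0(position, "-", out))
}

#' FAHFA shorthand names
#'
#' `species_name()` renders the field's structural shorthand,
#' `"16:0-(9-O-18:0)"` (position omitted when unspecified);
#' `parse_species_name()` is its inverse.
#'
#' @param species A species tibble.
#' @return `species_name()`: character vector. `parse_species_name()`: a
#'   species tibble rebuilt from the names.
#' @examples
#' sp <- parse_species_name("18:1-(12-O-18:0)")
#' species_name(sp) # round-trips
#' @export
species_name <- function(species) {
  pos <- ifelse(is.na(species$hydroxyl_position), "",
                paste0(species$hydroxyl_position, "-"))
  sprintf("%d:%d-(%sO-%d:%d)", species$acyl_carbons, species$acyl_db,
          pos, species$backbone_carbons, species$backbone_db)
}

#' @rdname species_name
#' @param x Character vector of shorthand names, e.g. `"16:0-(O-18:1)"`.
#' @export
parse_species_name <- function(x) {
  m <- stringr::str_match(
    x, "^(\\d+):(\\d+)-\\((?:(\\d+)-)?O-(\\d+):(\\d+)\\)$"
  )
  if (anyNA(m[, 1])) {
    rlang::abort(paste0("unparseable FAHFA name: ", x[which(is.na(m[, 1]))[1]]))
  }
  new_species(
    acyl_carbons = as.integer(m[, 2]),
    acyl_db = as.integer(m[, 3]),
    backbone_carbons = as.integer(m[, 5]),
    backbone_db = as.integer(m[, 6]),
    hydroxyl_position = ifelse(is.na(m[, 4]), NA_integer_, as.integer(m[, 4]))
  )
}

#' Trivial abbreviation of a species under a panel
#'
#' Concatenates the panel abbreviations of the two moieties around "H"
#' (PA + H + OA = PAHOA), prefixed with the hydroxyl position when known
#' (9-PAHSA). Returns `NA` when either moiety has no panel abbreviation.
#'
#' @param species A species tibble.
#' @param panel A fatty acid panel supplying trivial abbreviations.
#' @return Character vector (NA where no abbreviation exists).
#' @examples
#' species_abbreviation(parse_species_name("18:2-(O-18:1)")) # "LAHOA"
#' @export
species_abbreviation <- function(species, panel = default_fa_panel()) {
  key <- paste(panel$carbons, panel$double_bonds)
  acyl <- panel$abbreviation[match(paste(species$acyl_carbons, species$acyl_db), key)]
  bb <- panel$abbreviation[match(paste(species$backbone_carbons, species$backbone_db), key)]
  combine_abbreviation(acyl, bb, species$hydroxyl_position)
}
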