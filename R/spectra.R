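# Rule-based negative-mode CID spectra. Every FAHFA yields four "general"
# ions (precursor, fatty acid anion, intact and dehydrated hydroxy fatty
# acid anions); position-specified saturated backbones additionally yield a
# diagnostic tail/head fragment pair whose m/z encodes the hydroxyl carbon.

#' General fragment ions of a FAHFA species
#'
#' The four major negative-mode CID ions: the \eqn{[M-H]^-} precursor, the
#' fatty acid fragment anion, and the hydroxy fatty acid fragment anion
#' together with its dehydration product.
#'
#' @param species A species tibble (rows are vectorised).
#' @return A tibble with columns `name`, `role`
#'   (`precursor`/`fa_anion`/`hfa_anion`/`hfa_dehydrated`) and `mz`,
#'   four rows per species.
#' @examples
#' general_fragment_ions(parse_species_name("16:0-(9-O-18:0)"))
#' @export
general_fragment_ions <- function(species) {
  hfa <- hfa_anion_mz(species$backbone_carbons, species$backbone_db)
  tibble::tibble(
    name = rep(species$name, each = 4L),
    role = rep(c("precursor", "fa_anion", "hfa_anion", "hfa_dehydrated"),
               nrow(species)),
    mz = as.vector(rbind(
      species$precursor_mz,
      fa_anion_mz(species$acyl_carbons, species$acyl_db),
      hfa$intact,
      hfa$dehydrated
    ))
  )
}

#' Hydroxyl-positional fragment ions
#'
#' For a saturated hydroxy backbone of n carbons with the hydroxyl at
#' carbon p, cleavage around the hydroxyl carbon yields a complementary
#' anion pair: the tail ion \eqn{C_{n-p+1}H_{2(n-p)+1}O^-} (methyl end) and
#' the head ion \eqn{C_{p-1}H_{2p-3}O^-} (carboxyl end). Their m/z is the
#' monoisotopic composition mass plus one electron. The tail m/z falls and
#' the head m/z rises by one CH2 (14.01565 Da) per position step, so the
#' pair localises the hydroxyl. Unsaturated backbones are not modelled.
#'
#' @param carbons Backbone chain length(s).
#' @param position Hydroxyl carbon position(s), in 2..(carbons - 1).
#' @param double_bonds Must be 0; present so callers can pass a backbone
#'   descriptor through unchanged.
#' @return A tibble with columns `tail_mz` and `head_mz`.
#' @examples
#' positional_fragment_mz(18, 9)  # tail 155.144, the 9-PAHSA diagnostic ion
#' positional_fragment_mz(18, 12) # pair near m/z 113 and 169
#' @export
positional_fragment_mz <- function(carbons, position, double_bonds = 0L) {
  if (any(double_bonds != 0L)) {
    rlang::abort("positional fragments are only modelled for saturated backbones")
  }
  n <- max(length(carbons), length(position))
  carbons <- vctrs::vec_recycle(as.integer(carbons), n)
  position <- vctrs::vec_recycle(as.integer(position), n)
  if (any(is.na(position) | position < 2L | position > carbons - 1L)) {
    rlang::abort("hydroxyl position must lie in 2..(n-1)")
  }
  tail_f <- elemental_formula(carbons - position + 1L,
                              2L * (carbons - position) + 1L, 1L)
  head_f <- elemental_formula(position - 1L, 2L * position - 3L, 1L)
  tibble::tibble(
    tail_mz = monoisotopic_mass(tail_f) + fahfa_masses$electron,
    head_mz = monoisotopic_mass(head_f) + fahfa_masses$electron
  )
}

#' Merge coincident peaks
#'
#' Peaks whose m/z fall within `tol` of each other are merged into one peak
#' at the summed intensity, keeping the m/z of the most intense member
#' (e.g. the fatty acid anion of 18:2 coincides exactly with the dehydrated
#' hydroxy-18:2 anion). Idempotent; input need not be sorted.
#'
#' @param peaks A tibble with columns `mz`, `intensity` and optionally
#'   `role` (roles of merged peaks are joined with "+").
#' @param tol Merge tolerance in Da.
#' @return A peaks tibble sorted by m/z.
#' @export
merge_coincident_peaks <- function(peaks, tol = 1e-4) {
  if (tol <= 0) rlang::abort("tol must be > 0")
  if (nrow(peaks) < 2) return(peaks)
  peaks <- dplyr::arrange(peaks, .data$mz)
  grp <- cumsum(c(TRUE, diff(peaks$mz) > tol))
  out <- peaks |>
    dplyr::mutate(.grp = grp) |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(
      mz = .data$mz[which.max(.data$intensity)],
      intensity = sum(.data$intensity),
      dplyr::across(dplyr::any_of("role"), ~paste(.x, collapse = "+")),
      .groups = "drop"
    ) |>
    dplyr::select(-".grp")
  out[names(peaks)[names(peaks) != ".grp"]]
}

#' Render in silico spectra for FAHFA species
#'
#' Maps each species' fragment ions to the template intensities for the
#' requested collision energy and acquisition mode, merges coincident
#' peaks, and rescales so the base peak is 100. Fragment-rich rendering
#' additionally emits the hydroxyl-positional ion pair and therefore
#' requires position-specified species with saturated backbones.
#'
#' @param species A species tibble (see [enumerate_general()]).
#' @param collision_energy Collision energy in V (one of the template's).
#' @param acquisition_mode `"profiling"` (4 spectra/s; general ions only)
#'   or `"fragment_rich"` (1 spectrum/s; adds positional ions).
#' @param template An intensity template tibble.
#' @param merge_tol Coincident-peak merge tolerance in Da.
#' @return A spectra tibble: the species columns plus `adduct`,
#'   `collision_energy`, `acquisition_mode`, `n_peaks`, and a `peaks`
#'   list-column of per-spectrum peak tibbles (`mz`, `intensity`, `role`,
#'   sorted by m/z, base peak = 100).
#' @examples
#' render_spectra(parse_species_name("16:0-(9-O-18:0)"), 40, "fragment_rich")
#' @export
render_spectra <- function(species, collision_energy, acquisition_mode = "profiling",
                           template = default_intensity_template(),
                           merge_tol = 1e-4) {
  acquisition_mode <- match.arg(acquisition_mode, c("profiling", "fragment_rich"))
  validate_template(template)
  cell <- template |>
    dplyr::filter(.data$acquisition_mode == !!acquisition_mode,
                  .data$collision_energy == !!collision_energy)
  if (nrow(cell) == 0) {
    rlang::abort(sprintf("template has no cell for %s at %s V",
                         acquisition_mode, format(collision_energy)))
  }
  if (acquisition_mode == "fragment_rich" &&
      (anyNA(species$hydroxyl_position) || any(species$backbone_db != 0L))) {
    rlang::abort(paste("fragment-rich spectra require species with a specified",
                       "hydroxyl position on a saturated backbone"))
  }

  ns <- nrow(species)
  hfa <- hfa_anion_mz(species$backbone_carbons, species$backbone_db)
  long <- tibble::tibble(
    idx = rep(seq_len(ns), 4L),
    role = rep(c("precursor", "fa_anion", "hfa_anion", "hfa_dehydrated"), each = ns),
    mz = c(species$precursor_mz,
           fa_anion_mz(species$acyl_carbons, species$acyl_db),
           hfa$intact, hfa$dehydrated)
  )
  if (acquisition_mode == "fragment_rich") {
    pos <- positional_fragment_mz(species$backbone_carbons, species$hydroxyl_position)
    long <- dplyr::bind_rows(long, tibble::tibble(
      idx = rep(seq_len(ns), 2L),
      role = rep(c("positional_tail", "positional_head"), each = ns),
      mz = c(pos$tail_mz, pos$head_mz)
    ))
  }
  long$intensity <- cell$intensity[match(long$role, cell$role)]
  long <- dplyr::filter(long, !is.na(.data$intensity))

  # vectorised coincidence merge + rescale across all spectra at once
  long <- dplyr::arrange(long, .data$idx, .data$mz)
  grp <- cumsum(c(TRUE, diff(long$mz) > merge_tol | diff(long$idx) != 0))
  merged <- long |>
    dplyr::mutate(.grp = grp) |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(
      idx = .data$idx[1],
      mz = .data$mz[which.max(.data$intensity)],
      intensity = sum(.data$intensity),
      role = paste(.data$role, collapse = "+"),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$idx) |>
    dplyr::mutate(intensity = .data$intensity / max(.data$intensity) * 100) |>
    dplyr::ungroup()

  peaks <- vctrs::vec_split(
    merged[c("mz", "intensity", "role")], merged$idx
  )$val
  out <- species
  out$adduct <- "[M-H]-"
  out$collision_energy <- as.numeric(collision_energy)
  out$acquisition_mode <- acquisition_mode
  out$n_peaks <- vapply(peaks, nrow, integer(1))
  out$peaks <- peaks
  out
}

#' Build the full in silico FAHFA library
#'
#' Profiling spectra (one per general species per collision energy) plus
#' fragment-rich 40 V spectra (one per positional species). With the
#' default 33-entry panel, backbone lengths and collision energies this
#' yields 1089 x 3 = 3267 profiling records and 4290 fragment-rich
#' records, 7557 spectra in total.
#'
#' @inheritParams enumerate_general
#' @inheritParams enumerate_positional
#' @param collision_energies Profiling collision energies in V.
#' @param modes Which record sets to build.
#' @param template Intensity template tibble.
#' @return A spectra tibble (class `fahfa_library`), ordered profiling
#'   first (collision-energy major), then fragment-rich.
#' @examples
#' lib <- build_library(default_fa_panel()[1:2, ], lengths = c(14))
#' nrow(lib) # 2^2 * 3 profiling + 2 * 12 fragment-rich = 36
#' @export
build_library <- function(panel = default_fa_panel(),
                          lengths = default_positional_lengths(),
                          collision_energies = c(10, 20, 40),
                          modes = c("profiling", "fragment_rich"),
                          template = default_intensity_template()) {
  modes <- match.arg(modes, c("profiling", "fragment_rich"), several.ok = TRUE)
  parts <- list()
  if ("profiling" %in% modes) {
    general <- enumerate_general(panel)
    parts <- c(parts, purrr::map(
      collision_energies,
      ~render_spectra(general, .x, "profiling", template)
    ))
  }
  if ("fragment_rich" %in% modes) {
    positional <- enumerate_positional(panel, lengths)
    parts <- c(parts, list(render_spectra(positional, 40, "fragment_rich", template)))
  }
  lib <- dplyr::bind_rows(parts)
  class(lib) <- c("fahfa_library", class(lib))
  lib
}
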