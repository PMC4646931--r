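#' Relative-intensity templates for in silico CID spectra
#'
#' Each (collision energy, acquisition mode) cell maps ion roles to
#' relative intensities on a 0-100 scale. The defaults encode the
#' qualitative behaviour of the 9-PAHSA reference spectra: precursor
#' intensity falls monotonically with collision energy, the fatty acid
#' anion dominates at 20 and 40 V, and the two hydroxyl-positional
#' fragments appear only in fragment-rich (1 spectrum/s) acquisition at
#' 40 V, at the 0.2 %/0.1 % abundances observed for the diagnostic ion
#' pairs. No absolute intensities for the major peaks are published, so
#' those values are package defaults and fully user-configurable through
#' a YAML template file.
#'
#' @return A tibble with columns `acquisition_mode`, `collision_energy`,
#'   `role`, `intensity`.
#' @examples
#' default_intensity_template()
#' @export
default_intensity_template <- function() {
  profiling <- tibble::tribble(
    ~collision_energy, ~role, ~intensity,
    10, "precursor", 100, 10, "fa_anion", 30, 10, "hfa_anion", 10, 10, "hfa_dehydrated", 5,
    20, "precursor", 40, 20, "fa_anion", 100, 20, "hfa_anion", 30, 20, "hfa_dehydrated", 15,
    40, "precursor", 2, 40, "fa_anion", 100, 40, "hfa_anion", 25, 40, "hfa_dehydrated", 20
  )
  rich <- dplyr::bind_rows(
    dplyr::filter(profiling, .data$collision_energy == 40),
    tibble::tribble(
      ~collision_energy, ~role, ~intensity,
      40, "positional_tail", 0.2,
      40, "positional_head", 0.1
    )
  )
  dplyr::bind_rows(
    dplyr::mutate(profiling, acquisition_mode = "profiling"),
    dplyr::mutate(rich, acquisition_mode = "fragment_rich")
  ) |>
    dplyr::relocate("acquisition_mode") |>
    validate_template()
}

validate_template <- function(template) {
  required <- c("acquisition_mode", "collision_energy", "role", "intensity")
  if (!all(required %in% names(template))) {
    rlang::abort("template must have acquisition_mode, collision_energy, role, intensity")
  }
  if (any(template$intensity <= 0 | template$intensity > 100)) {
    rlang::abort("template intensities must lie in (0, 100]")
  }
  prec <- template |>
    dplyr::filter(.data$role == "precursor") |>
    dplyr::group_by(.data$acquisition_mode) |>
    dplyr::arrange(.data$collision_energy, .by_group = TRUE) |>
    dplyr::summarise(ok = all(diff(.data$intensity) < 0) || dplyr::n() == 1,
                     .groups = "drop")
  if (!all(prec$ok)) {
    rlang::abort("precursor intensity must strictly decrease with collision energy")
  }
  pos <- dplyr::filter(template, startsWith(.data$role, "positional"))
  if (any(pos$acquisition_mode != "fragment_rich") || any(pos$intensity > 1)) {
    rlang::abort("positional roles belong to fragment_rich mode with intensity <= 1")
  }
  template
}

#' Read or write an intensity template as YAML
#'
#' The file maps acquisition mode, then collision energy, then ion role to
#' intensity, e.g. `profiling: {"20": {precursor: 40, fa_anion: 100, ...}}`.
#'
#' @param path File path.
#' @return `read_intensity_template()` returns a validated template tibble.
#' @export
read_intensity_template <- function(path) {
  doc <- yaml::read_yaml(path)
  purrr::imap(doc, function(ces, mode) {
    purrr::imap(ces, function(roles, ce) {
      tibble::tibble(
        acquisition_mode = mode,
        collision_energy = as.numeric(ce),
        role = names(roles),
        intensity = as.numeric(unlist(roles))
      )
    }) |> dplyr::bind_rows()
  }) |>
    dplyr::bind_rows() |>
    validate_template()
}

#' @rdname read_intensity_template
#' @param template A template tibble.
#' @export
write_intensity_template <- function(template, path) {
  validate_template(template)
  doc <- split(template, template$acquisition_mode) |>
    purrr::map(function(mode_df) {
      split(mode_df, format(mode_df$collision_energy)) |>
        purrr::map(~as.list(stats::setNames(.x$intensity, .x$role)))
    })
  yaml::write_yaml(doc, path)
  invisible(path)
}
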