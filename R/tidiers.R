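#' Tidy an in silico library into a long peak table
#'
#' One row per peak across all spectra: record metadata (`name`,
#' `collision_energy`, `acquisition_mode`, `precursor_mz`) plus `mz`,
#' `intensity` and ion `role`.
#'
#' @param x A `fahfa_library` tibble.
#' @param ... Unused.
#' @return A tibble of peaks.
#' @exportS3Method generics::tidy
tidy.fahfa_library <- function(x, ...) {
  x |>
    dplyr::select("name", "abbreviation", "collision_energy",
                  "acquisition_mode", "precursor_mz", "peaks") |>
    tidyr::unnest("peaks")
}

#' Summarise an in silico library
#'
#' @param x A `fahfa_library` tibble.
#' @param ... Unused.
#' @return A one-row tibble: record counts overall and per acquisition
#'   mode, distinct species, and the precursor m/z range.
#' @exportS3Method generics::glance
glance.fahfa_library <- function(x, ...) {
  tibble::tibble(
    n_spectra = nrow(x),
    n_profiling = sum(x$acquisition_mode == "profiling"),
    n_fragment_rich = sum(x$acquisition_mode == "fragment_rich"),
    n_species = dplyr::n_distinct(x$name),
    precursor_mz_min = min(x$precursor_mz),
    precursor_mz_max = max(x$precursor_mz)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
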