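#' Plot a single MS/MS spectrum
#'
#' Stick plot of one spectrum (a library record row or a query row), with
#' low-abundance peaks still visible thanks to a minimum segment of zero
#' and peak labels for the ion roles when present.
#'
#' @param spectrum A one-row spectra/query tibble with a `peaks`
#'   list-column.
#' @param label_roles Label peaks with their ion role when available.
#' @return A ggplot object.
#' @examples
#' plot_spectrum(render_spectra(parse_species_name("16:0-(9-O-18:0)"),
#'                              40, "fragment_rich"))
#' @export
plot_spectrum <- function(spectrum, label_roles = TRUE) {
  spectrum <- spectrum[1, ]
  pk <- spectrum$peaks[[1]]
  title <- spectrum$name %||% spectrum$title %||% ""
  p <- ggplot2::ggplot(pk, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0),
                          linewidth = 0.6) +
    ggplot2::labs(x = "m/z", y = "relative intensity (%)", title = title) +
    ggplot2::theme_minimal()
  if (label_roles && "role" %in% names(pk)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$role),
                                vjust = -0.4, size = 2.8)
  }
  p
}

#' Mirror plot of a query against a library spectrum
#'
#' Query peaks point up, reference peaks point down — the standard visual
#' check of a spectral-library match.
#'
#' @param query A one-row query tibble.
#' @param reference A one-row spectra tibble.
#' @return A ggplot object.
#' @export
plot_mirror <- function(query, reference) {
  qp <- dplyr::mutate(query[1, ]$peaks[[1]][c("mz", "intensity")],
                      which = "query")
  rp <- dplyr::mutate(reference[1, ]$peaks[[1]][c("mz", "intensity")],
                      intensity = -.data$intensity, which = "reference")
  ggplot2::ggplot(dplyr::bind_rows(qp, rp),
                  ggplot2::aes(x = .data$mz, y = .data$intensity,
                               colour = .data$which)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0),
                          linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "m/z", y = "relative intensity (%)", colour = NULL,
                  title = reference[1, ]$name %||% "") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Overview plot of an in silico library
#'
#' Precursor m/z distribution of the library records, split by acquisition
#' mode and coloured by collision energy.
#'
#' @param object A `fahfa_library` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fahfa_library <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$precursor_mz,
                               fill = factor(.data$collision_energy))) +
    ggplot2::geom_histogram(binwidth = 5, position = "stack") +
    ggplot2::facet_wrap(~acquisition_mode, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "precursor m/z", y = "spectra",
                  fill = "collision energy (V)") +
    ggplot2::theme_minimal()
}
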