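# Seeded fabrication of realistic query spectra: m/z jitter, multiplicative
# log-normal intensity noise, uniform background peaks, optional isotope
# satellites, and a flag that drops the positional fragment pair to emulate
# fast (4 spectra/s) profiling acquisition. Everything is driven by an
# explicit seed and leaves the caller's RNG state untouched.

#' Noise model for simulated query spectra
#'
#' @param mz_jitter_sd Gaussian m/z error SD in Da, applied to every peak
#'   and to the precursor (default 0.002, a typical QTOF calibration
#'   error).
#' @param intensity_cv Coefficient of variation of multiplicative
#'   log-normal intensity noise (default 0.2).
#' @param n_background_peaks Number of background peaks drawn uniformly in
#'   m/z over (50, precursor + 5).
#' @param background_intensity_max Upper bound of background peak
#'   intensity, in % of base peak (default 2; stray background peaks in
#'   real spectra are minor).
#' @param include_isotopes Add +1.00336/+2.00671 Da isotope satellites to
#'   every signal peak (off by default: isotope ions are excluded from the
#'   library model, but wide isolation windows let them into real spectra).
#' @param drop_positional_fragments Remove the hydroxyl-positional ion
#'   pair before adding noise, emulating 4 spectra/s profiling acquisition
#'   in which those 0.1-0.2 % ions are not observed.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(mz_jitter_sd = 0.002, intensity_cv = 0.2,
                        n_background_peaks = 5, background_intensity_max = 2,
                        include_isotopes = FALSE,
                        drop_positional_fragments = FALSE) {
  if (mz_jitter_sd < 0 || intensity_cv < 0 || n_background_peaks < 0 ||
      background_intensity_max < 0) {
    rlang::abort("noise rates must be >= 0")
  }
  structure(
    list(mz_jitter_sd = mz_jitter_sd, intensity_cv = intensity_cv,
         n_background_peaks = as.integer(n_background_peaks),
         background_intensity_max = background_intensity_max,
         include_isotopes = include_isotopes,
         drop_positional_fragments = drop_positional_fragments),
    class = "noise_model"
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a noisy query spectrum from a library record
#'
#' Takes a rendered in silico spectrum and perturbs it under a
#' [noise_model()]: optional removal of positional fragments, Gaussian m/z
#' jitter, log-normal intensity noise, uniform background peaks and
#' optional isotope satellites; the result is rescaled to base peak 100
#' and returned in query-tibble form ready for [annotate_batch()] or
#' [write_mgf()]. Identical seeds give identical spectra.
#'
#' @param record A single-row spectra tibble (one library record).
#' @param noise A [noise_model()].
#' @param seed Integer seed controlling all randomness in this call.
#' @return A one-row query tibble (`title`, `precursor_mz`, `charge`,
#'   `rt`, `n_peaks`, `peaks`).
#' @examples
#' lib <- render_spectra(parse_species_name("18:2-(O-18:1)"), 20)
#' simulate_query(lib[1, ], noise_model(), seed = 7)
#' @export
simulate_query <- function(record, noise = noise_model(), seed = 1L) {
  record <- record[1, ]
  peaks <- record$peaks[[1]]
  if (noise$drop_positional_fragments && "role" %in% names(peaks)) {
    peaks <- peaks[!grepl("positional", peaks$role), ]
  }
  with_seed(seed, {
    mz <- peaks$mz + stats::rnorm(nrow(peaks), 0, noise$mz_jitter_sd)
    sdlog <- sqrt(log(1 + noise$intensity_cv^2))
    intensity <- peaks$intensity *
      stats::rlnorm(nrow(peaks), -sdlog^2 / 2, sdlog)
    if (noise$include_isotopes) {
      mz <- c(mz, mz + 1.00336, mz + 2.00671)
      intensity <- c(intensity, intensity * 0.3, intensity * 0.06)
    }
    if (noise$n_background_peaks > 0) {
      mz <- c(mz, stats::runif(noise$n_background_peaks, 50,
                               record$precursor_mz + 5))
      intensity <- c(intensity,
                     stats::runif(noise$n_background_peaks, 0,
                                  noise$background_intensity_max))
    }
    pmz <- record$precursor_mz + stats::rnorm(1, 0, noise$mz_jitter_sd)
    out_peaks <- tibble::tibble(mz = mz,
                                intensity = intensity / max(intensity) * 100) |>
      dplyr::arrange(.data$mz)
    tibble::tibble(
      title = sprintf("sim|%s|%gV|%s|seed=%d", record$name,
                      record$collision_energy, record$acquisition_mode, seed),
      precursor_mz = pmz,
      charge = "1-",
      rt = NA_real_,
      n_peaks = nrow(out_peaks),
      peaks = list(out_peaks)
    )
  })
}

#' Reference-standard and application query fixtures
#'
#' A deterministic, noise-free query set built entirely from the
#' fragmentation rules: the four commercially available reference
#' standards — 9-PAHSA [16:0-(9-O-18:0)], 5-OAHSA [18:1-(5-O-18:0)],
#' 9-OAHSA [18:1-(9-O-18:0)] and 12-OAHSA [18:1-(12-O-18:0)] — at each
#' profiling collision energy (10/20/40 V) and in fragment-rich 40 V mode,
#' plus the six FAHFAs annotated in egg yolk (PAHOA, OAHOA, OAHLA, LAHOA,
#' LAHLA, ALAHOA) at 20 V profiling: 4 x 3 + 4 + 6 = 22 fixtures. These
#' are synthetic stand-ins for the corresponding experimental spectra.
#'
#' @param template Intensity template used for rendering.
#' @return A 22-row query tibble; titles encode standard, collision energy
#'   and mode, e.g. `"9-PAHSA/40V/fragment_rich"`.
#' @export
reference_fixtures <- function(template = default_intensity_template()) {
  standards <- c("9-PAHSA" = "16:0-(9-O-18:0)", "5-OAHSA" = "18:1-(5-O-18:0)",
                 "9-OAHSA" = "18:1-(9-O-18:0)", "12-OAHSA" = "18:1-(12-O-18:0)")
  egg_yolk <- c("PAHOA" = "16:0-(O-18:1)", "OAHOA" = "18:1-(O-18:1)",
                "OAHLA" = "18:1-(O-18:2)", "LAHOA" = "18:2-(O-18:1)",
                "LAHLA" = "18:2-(O-18:2)", "ALAHOA" = "18:3-(O-18:1)")
  plan <- dplyr::bind_rows(
    tidyr::expand_grid(label = names(standards), ce = c(10, 20, 40),
                       mode = "profiling") |>
      dplyr::mutate(name = standards[.data$label]),
    tibble::tibble(label = names(standards), ce = 40, mode = "fragment_rich",
                   name = standards),
    tibble::tibble(label = names(egg_yolk), ce = 20, mode = "profiling",
                   name = egg_yolk)
  )
  purrr::pmap(plan, function(label, ce, mode, name) {
    rec <- render_spectra(parse_species_name(name), ce, mode, template)
    pk <- rec$peaks[[1]][c("mz", "intensity")]
    tibble::tibble(
      title = sprintf("%s/%gV/%s", label, ce, mode),
      precursor_mz = rec$precursor_mz,
      charge = "1-",
      rt = NA_real_,
      n_peaks = nrow(pk),
      peaks = list(pk)
    )
  }) |> dplyr::bind_rows()
}
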