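# NIST MSP text dialect: colon-separated header keys, "Precursor_type:
# [M-H]-", peaks one per line as "mz intensity" (m/z to 5 decimals,
# intensity to 3 so the 0.1-0.2 % positional peaks survive), records
# separated by one blank line. Output carries no timestamps, so identical
# libraries serialize byte-identically.

#' Write a spectral library to NIST MSP format
#'
#' @param records A spectra tibble as produced by [build_library()] or
#'   [read_msp()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".msp")
#' write_msp(render_spectra(parse_species_name("16:0-(O-18:1)"), 20), f)
#' @export
write_msp <- function(records, path) {
  if (nrow(records) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  comment <- paste0(
    "mode=", records$acquisition_mode,
    ifelse(is.na(records$abbreviation), "",
           paste0(" abbreviation=", records$abbreviation))
  )
  headers <- paste0(
    "Name: ", records$name, "\n",
    "PrecursorMZ: ", sprintf("%.5f", records$precursor_mz), "\n",
    "Precursor_type: ", records$adduct, "\n",
    "Formula: ", records$formula, "\n",
    "Collision_energy: ", format(records$collision_energy, trim = TRUE), "\n",
    "Comment: ", comment, "\n",
    "Num Peaks: ", records$n_peaks
  )
  peak_block <- vapply(
    records$peaks,
    function(p) paste(sprintf("%.5f %.3f", p$mz, p$intensity), collapse = "\n"),
    character(1)
  )
  writeLines(paste0(headers, "\n", peak_block), path, sep = "\n\n")
  invisible(path)
}

#' Read a NIST MSP spectral library
#'
#' Tolerates unknown header keys, both `Num Peaks` and `NumPeaks`
#' spellings, comment lines starting with `#`, and extra blank lines. A
#' record whose declared peak count disagrees with its peak lines is an
#' error naming the record.
#'
#' @param path Path to an MSP file.
#' @return A spectra tibble; chain-descriptor columns are reconstructed
#'   from names in the `"16:0-(9-O-18:0)"` shorthand where possible.
#' @export
read_msp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  is_name <- grepl("^Name\\s*:", lines)
  if (!any(is_name)) return(empty_library())
  rec <- cumsum(is_name)
  keep <- rec > 0 & nzchar(trimws(lines))
  lines <- lines[keep]; rec <- rec[keep]

  has_colon <- grepl("^[A-Za-z][A-Za-z_ ]*:", lines)
  is_peak <- !has_colon & grepl("^\\s*[0-9.]", lines)

  key <- tolower(gsub("[ _]", "", sub(":.*$", "", lines[has_colon])))
  val <- trimws(sub("^[^:]*:", "", lines[has_colon]))
  hrec <- rec[has_colon]
  field <- function(k) {
    idx <- key == k
    out <- rep(NA_character_, max(rec))
    out[hrec[idx]] <- val[idx]
    out
  }

  name <- field("name")
  declared <- suppressWarnings(as.integer(field("numpeaks")))
  peak_rec <- rec[is_peak]
  counts <- tabulate(peak_rec, nbins = max(rec))
  bad <- which(!is.na(declared) & declared != counts)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "record '%s': Num Peaks declares %d but %d peak lines found",
      name[bad[1]], declared[bad[1]], counts[bad[1]]
    ))
  }

  toks <- strsplit(trimws(lines[is_peak]), "[ \t]+")
  mz <- as.numeric(vapply(toks, `[`, character(1), 1L))
  intensity <- as.numeric(vapply(toks, `[`, character(1), 2L))
  peaks <- vctrs::vec_split(tibble::tibble(mz = mz, intensity = intensity),
                            peak_rec)
  peak_list <- rep(list(tibble::tibble(mz = numeric(0), intensity = numeric(0))),
                   max(rec))
  peak_list[peaks$key] <- peaks$val

  comment <- field("comment")
  species <- parse_species_name_quietly(name)
  out <- tibble::tibble(
    name = name,
    abbreviation = stringr::str_match(comment, "abbreviation=(\\S+)")[, 2],
    acyl_carbons = species$acyl_carbons,
    acyl_db = species$acyl_db,
    backbone_carbons = species$backbone_carbons,
    backbone_db = species$backbone_db,
    hydroxyl_position = species$hydroxyl_position,
    formula = field("formula"),
    precursor_mz = as.numeric(field("precursormz")),
    adduct = field("precursortype"),
    collision_energy = as.numeric(field("collisionenergy")),
    acquisition_mode = stringr::str_match(comment, "mode=(\\S+)")[, 2],
    n_peaks = counts,
    peaks = peak_list
  )
  class(out) <- c("fahfa_library", class(out))
  out
}

parse_species_name_quietly <- function(x) {
  m <- stringr::str_match(x, "^(\\d+):(\\d+)-\\((?:(\\d+)-)?O-(\\d+):(\\d+)\\)$")
  tibble::tibble(
    acyl_carbons = as.integer(m[, 2]),
    acyl_db = as.integer(m[, 3]),
    backbone_carbons = as.integer(m[, 5]),
    backbone_db = as.integer(m[, 6]),
    hydroxyl_position = as.integer(m[, 4])
  )
}

empty_library <- function() {
  out <- tibble::tibble(
    name = character(0), abbreviation = character(0),
    acyl_carbons = integer(0), acyl_db = integer(0),
    backbone_carbons = integer(0), backbone_db = integer(0),
    hydroxyl_position = integer(0), formula = character(0),
    precursor_mz = numeric(0), adduct = character(0),
    collision_energy = numeric(0), acquisition_mode = character(0),
    n_peaks = integer(0), peaks = list()
  )
  class(out) <- c("fahfa_library", class(out))
  out
}
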