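# Mascot Generic Format: BEGIN IONS / END IONS blocks with TITLE, PEPMASS,
# optional CHARGE (expected 1- in negative mode) and RTINSECONDS, then one
# "mz intensity" pair per line. Stray blank lines between blocks are
# tolerated; a block without PEPMASS is an error reported with its line.

#' Read query MS/MS spectra from an MGF file
#'
#' @param path Path to an MGF file.
#' @return A query tibble with columns `title`, `precursor_mz`, `charge`,
#'   `rt` (seconds, `NA` when absent), `n_peaks`, and a `peaks`
#'   list-column of `mz`/`intensity` tibbles sorted by m/z.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begin <- which(trimws(lines) == "BEGIN IONS")
  end <- which(trimws(lines) == "END IONS")
  if (length(begin) != length(end) || any(begin > end)) {
    rlang::abort("unbalanced BEGIN IONS/END IONS blocks")
  }
  if (length(begin) == 0) return(empty_queries())
  purrr::map2(begin, end, function(b, e) {
    body <- lines[(b + 1):(e - 1)]
    body <- body[nzchar(trimws(body))]
    is_kv <- grepl("^[A-Za-z]+=", body)
    key <- toupper(sub("=.*$", "", body[is_kv]))
    val <- sub("^[^=]*=", "", body[is_kv])
    pep <- val[key == "PEPMASS"]
    if (length(pep) == 0) {
      rlang::abort(sprintf("MGF block starting at line %d lacks PEPMASS", b))
    }
    toks <- strsplit(trimws(body[!is_kv]), "[ \t]+")
    peaks <- tibble::tibble(
      mz = as.numeric(vapply(toks, `[`, character(1), 1L)),
      intensity = as.numeric(vapply(toks, `[`, character(1), 2L))
    ) |> dplyr::arrange(.data$mz)
    rt <- val[key == "RTINSECONDS"]
    ch <- val[key == "CHARGE"]
    tibble::tibble(
      title = if (any(key == "TITLE")) val[key == "TITLE"][1] else NA_character_,
      # PEPMASS may carry a second (intensity) token
      precursor_mz = as.numeric(strsplit(trimws(pep[1]), "[ \t]+")[[1]][1]),
      charge = if (length(ch) > 0) ch[1] else NA_character_,
      rt = if (length(rt) > 0) as.numeric(rt[1]) else NA_real_,
      n_peaks = nrow(peaks),
      peaks = list(peaks)
    )
  }) |> dplyr::bind_rows()
}

#' Write query spectra to an MGF file
#'
#' @param queries A query tibble (see [read_mgf()]).
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(queries, path) {
  blocks <- purrr::pmap_chr(
    list(queries$title, queries$precursor_mz,
         queries$charge %||% rep(NA_character_, nrow(queries)),
         queries$rt %||% rep(NA_real_, nrow(queries)),
         queries$peaks),
    function(title, pmz, charge, rt, peaks) {
      paste(c(
        "BEGIN IONS",
        if (!is.na(title)) paste0("TITLE=", title),
        paste0("PEPMASS=", sprintf("%.5f", pmz)),
        if (!is.na(charge)) paste0("CHARGE=", charge),
        if (!is.na(rt)) paste0("RTINSECONDS=", sprintf("%.3f", rt)),
        sprintf("%.5f %.4f", peaks$mz, peaks$intensity),
        "END IONS"
      ), collapse = "\n")
    }
  )
  writeLines(blocks, path, sep = "\n\n")
  invisible(path)
}

empty_queries <- function() {
  tibble::tibble(
    title = character(0), precursor_mz = numeric(0), charge = character(0),
    rt = numeric(0), n_peaks = integer(0), peaks = list()
  )
}
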