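# NIST-style spectral matching: precursor-window candidate retrieval, then
# square-root-intensity weighted cosine similarity scaled to 0-999 (the
# conventional open interpretation of the NIST dot product). The reverse
# variant drops query peaks with no counterpart in the reference from the
# query normalisation term, so chimeric/noise peaks in the query do not
# penalise the match. Absolute agreement with the closed-source NIST
# scores is not claimed; the >= 900 / >= 950 threshold semantics are.

#' Matching parameters
#'
#' @param precursor_tol Precursor window half-width in Da (default 0.005,
#'   matching the annotation tolerance used for FAHFA precursors).
#' @param fragment_tol Fragment alignment tolerance in Da.
#' @param intensity_power Exponent on intensity in the peak weight
#'   (0.5 = square-root weighting).
#' @param mz_power Exponent on m/z in the peak weight (0 = none).
#' @param min_reverse_dot Reporting threshold on the reverse dot score.
#' @return A list of class `match_params`.
#' @export
match_params <- function(precursor_tol = 0.005, fragment_tol = 0.01,
                         intensity_power = 0.5, mz_power = 0,
                         min_reverse_dot = 900) {
  if (precursor_tol <= 0 || fragment_tol <= 0) {
    rlang::abort("tolerances must be > 0")
  }
  if (intensity_power < 0 || mz_power < 0) rlang::abort("powers must be >= 0")
  if (min_reverse_dot < 0 || min_reverse_dot > 999) {
    rlang::abort("min_reverse_dot must lie in 0..999")
  }
  structure(
    list(precursor_tol = precursor_tol, fragment_tol = fragment_tol,
         intensity_power = intensity_power, mz_power = mz_power,
         min_reverse_dot = min_reverse_dot),
    class = "match_params"
  )
}

#' Align two peak lists
#'
#' Greedy nearest-m/z pairing within `fragment_tol`: candidate pairs are
#' taken in order of |delta m/z|, each peak used at most once. On small
#' spectra this agrees with the optimal one-to-one assignment minimising
#' the total m/z deviation.
#'
#' @param query,reference Peak tibbles (`mz`, `intensity`), sorted by m/z.
#' @param fragment_tol Pairing tolerance in Da.
#' @return A tibble of pairs sorted by query m/z: `query_idx`, `ref_idx`,
#'   `query_mz`, `ref_mz`, `query_intensity`, `ref_intensity`.
#' @export
align_peaks <- function(query, reference, fragment_tol = 0.01) {
  idx <- align_idx(query$mz, reference$mz, fragment_tol)
  qi <- as.vector(idx[, 1]); ri <- as.vector(idx[, 2])
  out <- tibble::tibble(
    query_idx = qi, ref_idx = ri,
    query_mz = query$mz[qi], ref_mz = reference$mz[ri],
    query_intensity = query$intensity[qi],
    ref_intensity = reference$intensity[ri]
  )
  dplyr::arrange(out, .data$query_mz)
}

# greedy nearest-m/z one-to-one pairing on plain vectors (hot path)
align_idx <- function(qmz, rmz, tol) {
  nq <- length(qmz); nr <- length(rmz)
  if (nq == 0 || nr == 0) {
    return(cbind(q = integer(0), r = integer(0)))
  }
  qi <- rep.int(seq_len(nq), nr)
  ri <- rep(seq_len(nr), each = nq)
  d <- abs(qmz[qi] - rmz[ri])
  keep <- d <= tol
  if (!any(keep)) return(cbind(q = integer(0), r = integer(0)))
  qi <- qi[keep]; ri <- ri[keep]
  o <- order(d[keep], qi, ri)
  qi <- qi[o]; ri <- ri[o]
  used_q <- logical(nq); used_r <- logical(nr)
  kp <- logical(length(qi))
  for (i in seq_along(qi)) {
    if (!used_q[qi[i]] && !used_r[ri[i]]) {
      kp[i] <- TRUE
      used_q[qi[i]] <- TRUE
      used_r[ri[i]] <- TRUE
    }
  }
  cbind(q = qi[kp], r = ri[kp])
}

peak_weights <- function(peaks, params) {
  peaks$intensity^params$intensity_power *
    (if (params$mz_power == 0) 1 else peaks$mz^params$mz_power)
}

#' Forward and reverse dot-product similarity
#'
#' Weighted cosine similarity on 0-999: with peak weights
#' \eqn{w = I^{a} m/z^{b}}, the score is
#' \eqn{999 (\sum_{matched} w_q w_r)^2 / (\sum w_q^2 \sum w_r^2)}, rounded
#' to an integer. `dot_score()` normalises over all peaks of both spectra
#' (symmetric); `reverse_dot_score()` excludes unmatched query peaks from
#' the query normalisation, so extra query peaks (noise, co-eluting ions)
#' do not lower the score and reverse >= forward always holds.
#'
#' @inheritParams align_peaks
#' @param params A [match_params()] list.
#' @return Integer score in 0..999.
#' @examples
#' pk <- render_spectra(parse_species_name("16:0-(O-18:1)"), 20)$peaks[[1]]
#' dot_score(pk, pk) # 999
#' @export
dot_score <- function(query, reference, params = match_params()) {
  as.integer(round(score_impl(query, reference, params, reverse = FALSE)))
}

#' @rdname dot_score
#' @export
reverse_dot_score <- function(query, reference, params = match_params()) {
  as.integer(round(score_impl(query, reference, params, reverse = TRUE)))
}

# full-precision similarity on the 0-999 scale; the exported scores round
# it to the conventional integer, ranking keeps the full precision so
# near-ties (e.g. mirror-position positional isomers, whose diagnostic
# pairs share m/z and differ only in the 0.2/0.1 intensity order) are
# still ordered by the actual similarity
score_impl <- function(query, reference, params, reverse) {
  if (nrow(query) == 0 || nrow(reference) == 0) {
    rlang::abort("cannot score an empty spectrum")
  }
  s <- score_pair(query$mz, peak_weights(query, params),
                  reference$mz, peak_weights(reference, params),
                  params$fragment_tol)
  if (reverse) s[2] else s[1]
}

# forward and reverse full-precision scores from one alignment
score_pair <- function(qmz, wq, rmz, wr, tol) {
  idx <- align_idx(qmz, rmz, tol)
  if (nrow(idx) == 0) return(c(0, 0))
  num <- sum(wq[idx[, 1]] * wr[idx[, 2]])^2
  r_norm <- sum(wr^2)
  fwd <- 999 * min(num / (sum(wq^2) * r_norm), 1)
  rev <- 999 * min(num / (sum(wq[idx[, 1]]^2) * r_norm), 1)
  c(fwd, rev)
}

#' Retrieve library candidates by precursor m/z
#'
#' Binary-search retrieval of all records whose precursor m/z lies within
#' `precursor_tol` of the query precursor.
#'
#' @param library A spectra tibble ([build_library()] / [read_msp()]).
#' @param query_precursor_mz Query precursor m/z.
#' @param precursor_tol Window half-width in Da.
#' @return The matching library rows.
#' @export
candidates_by_precursor <- function(library, query_precursor_mz,
                                    precursor_tol = 0.005) {
  ord <- order(library$precursor_mz)
  sorted <- library$precursor_mz[ord]
  # indices with |precursor - query| <= tol, both bounds inclusive
  lo <- findInterval(query_precursor_mz - precursor_tol, sorted,
                     left.open = TRUE) + 1L
  hi <- findInterval(query_precursor_mz + precursor_tol, sorted)
  if (hi < lo) return(library[integer(0), ])
  library[sort(ord[lo:hi]), ]
}

#' Annotate query spectra against an in silico library
#'
#' For each query: candidates within the precursor window are scored
#' (forward and reverse dot), ranked by reverse dot score (ties broken by
#' forward dot, then |precursor error|, then name, so reports are fully
#' reproducible) and thresholded at `min_reverse_dot`.
#'
#' @param queries A query tibble (see [read_mgf()] / [simulate_query()]).
#' @param library A spectra tibble.
#' @param params A [match_params()] list.
#' @return A tibble of hits: `query_title`, `query_precursor_mz`, `rank`,
#'   `hit_name`, `hit_abbreviation`, `hit_collision_energy`, `hit_mode`,
#'   `hit_precursor_mz`, `delta_mz_mda`, `dot`, `reverse_dot`. Queries
#'   with no passing candidate contribute no rows.
#' @examples
#' lib <- build_library(default_fa_panel()[c(5, 10), ], lengths = 14)
#' q <- simulate_query(lib[4, ], seed = 1)
#' annotate_batch(q, lib)
#' @export
annotate_batch <- function(queries, library, params = match_params()) {
  ord <- order(library$precursor_mz)
  sorted_mz <- library$precursor_mz[ord]
  purrr::map(seq_len(nrow(queries)), function(i) {
    q <- queries[i, ]
    lo <- findInterval(q$precursor_mz - params$precursor_tol, sorted_mz,
                       left.open = TRUE) + 1L
    hi <- findInterval(q$precursor_mz + params$precursor_tol, sorted_mz)
    if (hi < lo) return(NULL)
    cand <- library[ord[lo:hi], ]
    fwd <- vapply(cand$peaks,
                  function(r) score_impl(q$peaks[[1]], r, params, FALSE),
                  numeric(1))
    rev <- vapply(cand$peaks,
                  function(r) score_impl(q$peaks[[1]], r, params, TRUE),
                  numeric(1))
    hits <- tibble::tibble(
      query_title = q$title %||% NA_character_,
      query_precursor_mz = q$precursor_mz,
      hit_name = cand$name,
      hit_abbreviation = cand$abbreviation,
      hit_collision_energy = cand$collision_energy,
      hit_mode = cand$acquisition_mode,
      hit_precursor_mz = cand$precursor_mz,
      delta_mz_mda = (q$precursor_mz - cand$precursor_mz) * 1000,
      dot = as.integer(round(fwd)),
      reverse_dot = as.integer(round(rev)),
      .fwd = fwd, .rev = rev
    )
    hits <- hits[hits$reverse_dot >= params$min_reverse_dot, ]
    if (nrow(hits) == 0) return(NULL)
    hits <- dplyr::arrange(hits, dplyr::desc(.data$.rev),
                           dplyr::desc(.data$.fwd), abs(.data$delta_mz_mda),
                           .data$hit_name)
    hits$rank <- seq_len(nrow(hits))
    hits <- dplyr::select(hits, -".fwd", -".rev")
    dplyr::relocate(hits, "rank", .after = "query_precursor_mz")
  }) |> dplyr::bind_rows()
}

#' @rdname annotate_batch
#' @param query A single-row query tibble.
#' @export
annotate <- function(query, library, params = match_params()) {
  annotate_batch(query[1, ], library, params)
}

#' Write an annotation report as TSV
#'
#' One row per retained hit, mirroring tabular batch-search output:
#' `query_title`, `query_precursor_mz`, `rank`, `hit_name`,
#' `hit_abbreviation`, `hit_precursor_mz`, `delta_mz_mDa`, `dot`,
#' `reverse_dot`. An empty result set yields a header-only file.
#'
#' @param results Hits tibble from [annotate_batch()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_annotation_report <- function(results, path) {
  col <- function(nm, default) {
    if (nm %in% names(results)) results[[nm]] else default
  }
  out <- tibble::tibble(
    query_title = col("query_title", character(0)),
    query_precursor_mz = sprintf("%.5f", col("query_precursor_mz", numeric(0))),
    rank = col("rank", integer(0)),
    hit_name = col("hit_name", character(0)),
    hit_abbreviation = col("hit_abbreviation", character(0)),
    hit_precursor_mz = sprintf("%.5f", col("hit_precursor_mz", numeric(0))),
    delta_mz_mDa = sprintf("%.3f", col("delta_mz_mda", numeric(0))),
    dot = col("dot", integer(0)),
    reverse_dot = col("reverse_dot", integer(0))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
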