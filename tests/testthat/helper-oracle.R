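# Independent oracles, deliberately coded apart from the package internals.

# second, independently sourced monoisotopic mass table (CODATA values at
# higher precision than the package constants)
oracle_mass <- function(c, h, o) {
  c * 12 + h * 1.00782503207 + o * 15.9949146196
}
oracle_deprotonated <- function(c, h, o) {
  oracle_mass(c, h, o) - 1.00727646688
}

# brute-force optimal one-to-one peak assignment minimising total |delta mz|,
# then the weighted cosine on that assignment (for <= 5-peak spectra)
oracle_dot <- function(query, reference, tol = 0.01, power = 0.5) {
  nq <- nrow(query); nr <- nrow(reference)
  wq <- query$intensity^power
  wr <- reference$intensity^power
  best <- NULL; best_cost <- Inf
  assignments <- function(qs, used_r, pairs, cost) {
    if (length(qs) == 0) {
      if (cost < best_cost ||
          (cost == best_cost && length(pairs) > length(best))) {
        best <<- pairs; best_cost <<- cost
      }
      return(invisible())
    }
    q1 <- qs[1]
    # leave q1 unmatched (penalise so maximal matchings win)
    assignments(qs[-1], used_r, pairs, cost + tol * 10)
    for (r in seq_len(nr)) {
      d <- abs(query$mz[q1] - reference$mz[r])
      if (!used_r[r] && d <= tol) {
        used_r2 <- used_r; used_r2[r] <- TRUE
        assignments(qs[-1], used_r2, c(pairs, list(c(q1, r))), cost + d)
      }
    }
  }
  assignments(seq_len(nq), logical(nr), list(), 0)
  if (length(best) == 0) return(0)
  num <- sum(vapply(best, function(p) wq[p[1]] * wr[p[2]], numeric(1)))^2
  round(999 * num / (sum(wq^2) * sum(wr^2)))
}

# brute-force nested-loop count of the positional structure space
oracle_positional_count <- function(n_acyl, lengths) {
  count <- 0
  for (a in seq_len(n_acyl)) {
    for (n in lengths) {
      for (p in 2:(n - 1)) count <- count + 1
    }
  }
  count
}

# random small peak tibble for fuzz/property tests
random_peaks <- function(n, mz_range = c(100, 600)) {
  tibble::tibble(
    mz = sort(stats::runif(n, mz_range[1], mz_range[2])),
    intensity = stats::runif(n, 1, 100)
  )
}

# full default library, built once per test run
test_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_library()
    cache
  }
})
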