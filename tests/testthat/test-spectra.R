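test_that("the four general fragment ions are where chemistry puts them", {
  ions <- general_fragment_ions(parse_species_name("16:0-(9-O-18:0)"))
  expect_identical(ions$role,
                   c("precursor", "fa_anion", "hfa_anion", "hfa_dehydrated"))
  expect_equal(ions$mz, c(537.48883, 255.23295, 299.25917, 281.24860),
               tolerance = 1e-5)

  lahoa <- general_fragment_ions(parse_species_name("18:2-(O-18:1)"))
  expect_equal(lahoa$mz, c(559.47318, 279.23295, 297.24352, 279.23295),
               tolerance = 1e-5)
  # fa anion of 18:2 coincides exactly with dehydrated hydroxy-18:2... of the
  # 18:1 backbone's dehydration product
  expect_equal(lahoa$mz[2], lahoa$mz[4], tolerance = 1e-9)

  # precursor always dominates the fragment m/z range
  sp <- enumerate_general(default_fa_panel()[c(1, 15, 33), ])
  ions <- general_fragment_ions(sp)
  top <- tapply(ions$mz, ions$name, max)
  prec <- tapply(ions$mz[ions$role == "precursor"], ions$name[ions$role == "precursor"], max)
  expect_equal(top, prec)
})

test_that("positional fragment pair anchors and homology hold", {
  p9 <- positional_fragment_mz(18, 9)
  expect_equal(round(p9$tail_mz, 3), 155.144) # the reported diagnostic ion
  expect_equal(p9$tail_mz, 155.14414, tolerance = 1e-5) # C10H19O-
  expect_equal(p9$head_mz, 127.11284, tolerance = 1e-5) # C8H15O-

  p12 <- positional_fragment_mz(18, 12)
  expect_equal(round(p12$tail_mz, 3), 113.097)
  expect_equal(round(p12$head_mz, 3), 169.160)

  # tail falls and head rises by one CH2 per position step; their sum is a
  # function of chain length only
  pp <- positional_fragment_mz(18, 2:17)
  expect_equal(diff(pp$tail_mz), rep(-fahfa_masses$CH2, 15), tolerance = 1e-9)
  expect_equal(diff(pp$head_mz), rep(fahfa_masses$CH2, 15), tolerance = 1e-9)
  expect_equal(diff(pp$tail_mz + pp$head_mz), rep(0, 15), tolerance = 1e-9)

  expect_error(positional_fragment_mz(18, 9, double_bonds = 1), "saturated")
  expect_error(positional_fragment_mz(18, 18), "2\\.\\.")
})

test_that("coincident peak merging sums intensity and is idempotent", {
  pk <- tibble::tibble(mz = c(279.23295, 279.23295), intensity = c(100, 15))
  merged <- merge_coincident_peaks(pk)
  expect_identical(nrow(merged), 1L)
  expect_equal(merged$intensity, 115)
  expect_equal(merged$mz, 279.23295)

  disjoint <- tibble::tibble(mz = c(100, 200, 300), intensity = c(1, 2, 3))
  expect_equal(merge_coincident_peaks(disjoint), disjoint)
  expect_equal(merge_coincident_peaks(disjoint[2, ]), disjoint[2, ])
  expect_equal(merge_coincident_peaks(merge_coincident_peaks(pk)), merged)
  expect_error(merge_coincident_peaks(pk, tol = 0), "> 0")
})

test_that("rendering fills peaks from the template and rescales to 100", {
  rich <- render_spectra(parse_species_name("16:0-(9-O-18:0)"), 40,
                         "fragment_rich")
  pk <- rich$peaks[[1]]
  expect_identical(nrow(pk), 6L)
  expect_equal(max(pk$intensity), 100)
  expect_true(all(diff(pk$mz) > 0))
  # positional pair present at their reported sub-percent abundances
  tail_row <- pk[pk$role == "positional_tail", ]
  expect_equal(round(tail_row$mz, 3), 155.144)
  expect_lte(tail_row$intensity, 0.2)
  expect_lte(pk$intensity[pk$role == "positional_head"], 0.2)
  expect_equal(rich$precursor_mz, pk$mz[pk$role == "precursor"],
               tolerance = 1e-9)

  # coincidence merge: 3 peaks at 20 V profiling for 18:2-(O-18:1)
  lahoa <- render_spectra(parse_species_name("18:2-(O-18:1)"), 20)
  expect_identical(lahoa$n_peaks, 3L)
  base <- lahoa$peaks[[1]][which.max(lahoa$peaks[[1]]$intensity), ]
  expect_equal(base$mz, 279.23295, tolerance = 1e-5)
  expect_identical(base$role, "fa_anion+hfa_dehydrated")

  # precursor relative intensity strictly decreases with collision energy
  sp <- parse_species_name("16:0-(O-18:0)")
  prec_int <- vapply(c(10, 20, 40), function(ce) {
    pk <- render_spectra(sp, ce)$peaks[[1]]
    pk$intensity[pk$role == "precursor"]
  }, numeric(1))
  expect_true(all(diff(prec_int) < 0))

  expect_error(render_spectra(sp, 40, "fragment_rich"), "hydroxyl position")
  expect_error(render_spectra(sp, 15), "no cell")
})

test_that("rendering is deterministic", {
  sp <- enumerate_positional(default_fa_panel()[9:11, ], lengths = c(16, 18))
  a <- render_spectra(sp, 40, "fragment_rich")
  b <- render_spectra(sp, 40, "fragment_rich")
  expect_identical(a, b)
})

test_that("library assembly has the right shape and peak-count envelope", {
  lib <- build_library(default_fa_panel()[c(5, 10, 11), ], lengths = c(14, 18))
  expect_identical(nrow(lib), as.integer(9 * 3 + 3 * (12 + 16)))
  prof <- lib[lib$acquisition_mode == "profiling", ]
  rich <- lib[lib$acquisition_mode == "fragment_rich", ]
  expect_true(all(prof$n_peaks >= 3 & prof$n_peaks <= 4))
  # 6 roles minus coincidence merges; 4 only in the double-coincidence case
  # (n:1 acyl on O-n:0 backbone, hydroxyl at the chain midpoint)
  expect_true(all(rich$n_peaks >= 4 & rich$n_peaks <= 6))
  expect_identical(sum(rich$n_peaks == 4L), 1L) # 18:1-(10-O-18:0)
  expect_identical(rich$name[rich$n_peaks == 4L], "18:1-(10-O-18:0)")
  expect_true(all(rich$collision_energy == 40))
  expect_s3_class(lib, "fahfa_library")

  g <- glance(lib)
  expect_identical(g$n_spectra, nrow(lib))
  expect_identical(g$n_profiling + g$n_fragment_rich, nrow(lib))
  long <- tidy(lib)
  expect_identical(nrow(long), sum(lib$n_peaks))
})

test_that("template validation enforces the collision-energy behaviour", {
  tpl <- default_intensity_template()
  bad <- tpl
  bad$intensity[bad$acquisition_mode == "profiling" &
                  bad$role == "precursor"] <- c(10, 40, 50)
  expect_error(render_spectra(parse_species_name("16:0-(O-18:0)"), 20,
                              template = bad), "strictly decrease")

  f <- withr::local_tempfile(fileext = ".yaml")
  write_intensity_template(tpl, f)
  back <- read_intensity_template(f)
  expect_equal(
    dplyr::arrange(back, acquisition_mode, collision_energy, role),
    dplyr::arrange(tpl, acquisition_mode, collision_energy, role)
  )
})
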