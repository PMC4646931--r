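test_that("default panel has 33 unique fatty acids from 14:0 to 24:6", {
  p <- default_fa_panel()
  expect_identical(nrow(p), 33L)
  expect_false(any(duplicated(paste(p$carbons, p$double_bonds))))
  expect_identical(c(p$carbons[1], p$double_bonds[1]), c(14L, 0L))
  expect_identical(c(p$carbons[33], p$double_bonds[33]), c(24L, 6L))
  expect_true(all(c("PA", "SA", "OA", "LA", "ALA") %in% p$abbreviation))
})

test_that("panel reader round-trips the shipped panel and rejects bad input", {
  shipped <- system.file("extdata", "fa_panel_33.tsv", package = "fahfalib")
  expect_equal(read_fa_panel(shipped), default_fa_panel())

  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("carbons\tdouble_bonds\tabbreviation\tname", tmp)
  expect_error(read_fa_panel(tmp), "empty")

  writeLines(c("carbons\tdouble_bonds\tabbreviation\tname",
               "16\t0\tPA\tpalmitic acid",
               "16\t0\tPA\tpalmitic acid"), tmp)
  expect_error(read_fa_panel(tmp), "duplicate.*row 2")

  writeLines(c("carbons\tdouble_bonds\tabbreviation\tname",
               "16\tx\tPA\tpalmitic acid"), tmp)
  expect_error(read_fa_panel(tmp), "malformed.*row 1")
})

test_that("general enumeration yields all ordered pairs in stable order", {
  expect_identical(nrow(enumerate_general(default_fa_panel())), 1089L)

  one <- enumerate_general(default_fa_panel()[5, ]) # 16:0 only
  expect_identical(one$name, "16:0-(O-16:0)")

  two <- enumerate_general(default_fa_panel()[c(5, 10), ]) # 16:0, 18:1
  expect_identical(nrow(two), 4L)
  expect_true(all(c("16:0-(O-18:1)", "18:1-(O-16:0)") %in% two$name))

  # |panel|^2 for panels of several sizes; acyl-major order
  for (k in c(2, 5, 9)) {
    sub <- default_fa_panel()[seq_len(k), ]
    g <- enumerate_general(sub)
    expect_identical(nrow(g), as.integer(k^2))
    expect_identical(g$acyl_carbons[seq_len(k)], rep(sub$carbons[1], k))
  }
  expect_error(enumerate_general(default_fa_panel()[0, ]), "non-empty")
})

test_that("positional enumeration matches the nested-loop oracle", {
  expect_identical(nrow(enumerate_positional()), 4290L)
  expect_identical(sum(default_positional_lengths() - 2L), 130L)

  oahsa <- enumerate_positional(default_fa_panel()[10, ], lengths = 18)
  expect_identical(nrow(oahsa), 16L) # p = 2..17
  expect_true("18:1-(9-O-18:0)" %in% oahsa$name)
  # backbone abbreviation resolves when the panel carries the saturated chain
  both <- enumerate_positional(default_fa_panel()[9:10, ], lengths = 18)
  expect_identical(
    both$abbreviation[both$name == "18:1-(9-O-18:0)"], "9-OAHSA")

  tiny <- enumerate_positional(default_fa_panel()[1:3, ], lengths = 4)
  expect_identical(nrow(tiny), 6L) # 2 positions per acyl
  expect_setequal(unique(tiny$hydroxyl_position), c(2L, 3L))

  set.seed(5)
  for (i in 1:5) {
    k <- sample(1:6, 1)
    lens <- sort(sample(c(4:10, 14, 18), sample(1:3, 1)))
    got <- nrow(enumerate_positional(default_fa_panel()[seq_len(k), ], lens))
    expect_identical(got, as.integer(oracle_positional_count(k, lens)))
  }
  expect_error(enumerate_positional(lengths = 3), ">= 4")
})

test_that("every enumerated species satisfies the ester formula", {
  sp <- dplyr::bind_rows(
    enumerate_general(default_fa_panel()[c(1, 10, 20, 33), ]),
    enumerate_positional(default_fa_panel()[c(1, 33), ], lengths = c(14, 18))
  )
  frm <- fahfa_formula(sp$acyl_carbons, sp$acyl_db,
                       sp$backbone_carbons, sp$backbone_db)
  expect_identical(frm$c, sp$acyl_carbons + sp$backbone_carbons)
  expect_identical(frm$h, 2L * (sp$acyl_carbons + sp$backbone_carbons) -
                     2L * (sp$acyl_db + sp$backbone_db) - 2L)
  expect_identical(frm$o, rep(4L, nrow(sp)))
  expect_equal(sp$precursor_mz, deprotonated_mz(frm), tolerance = 1e-9)
})

test_that("species names follow the shorthand and round-trip", {
  expect_identical(
    species_name(parse_species_name("16:0-(O-18:1)")), "16:0-(O-18:1)")
  sp <- parse_species_name(
    c("16:0-(9-O-18:0)", "18:1-(12-O-18:0)", "18:2-(O-18:1)"))
  expect_identical(species_name(sp),
                   c("16:0-(9-O-18:0)", "18:1-(12-O-18:0)", "18:2-(O-18:1)"))
  # round-trip over a generated set
  gen <- enumerate_positional(default_fa_panel()[8:12, ], lengths = c(14, 16))
  back <- parse_species_name(gen$name)
  expect_identical(back$acyl_carbons, gen$acyl_carbons)
  expect_identical(back$hydroxyl_position, gen$hydroxyl_position)
  expect_identical(species_name(back), gen$name)
  expect_error(parse_species_name("not-a-fahfa"), "unparseable")
  expect_error(parse_species_name("16:0-(18-O-18:0)"), "2\\.\\.\\(n-1\\)")
})

test_that("trivial abbreviations concatenate around H with position prefix", {
  expect_identical(species_abbreviation(parse_species_name("18:2-(O-18:1)")),
                   "LAHOA")
  expect_identical(species_abbreviation(parse_species_name("18:3-(O-18:1)")),
                   "ALAHOA")
  expect_identical(species_abbreviation(parse_species_name("16:0-(9-O-18:0)")),
                   "9-PAHSA")
  # no trivial name for either moiety -> NA
  expect_true(is.na(species_abbreviation(parse_species_name("15:0-(O-17:0)"))))
})
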