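test_that("band-set distinguishability applies the co-migration tolerance", {
  m <- gel_model()
  expect_false(distinguishable(950, 950, m))
  expect_true(distinguishable(950, c(940, 220, 170), m))   # band count differs
  tol10 <- gel_model(comigration_tol = 0, comigration_floor = 10)
  expect_false(distinguishable(c(210, 180, 160), c(212, 178, 161), tol10))
  expect_true(distinguishable(c(210, 180, 160), c(212, 178, 130), tol10))
  # zero tolerance separates what the default gel cannot
  expect_true(distinguishable(c(210, 180, 160), c(212, 178, 161),
                              exact_gel_model()))
})

test_that("enzyme screening ranks by fraction of alleles cut", {
  set.seed(21)
  alleles <- stats::setNames(replicate(5, rand_dna(600)),
                             paste0("a", 1:5))
  catalogue <- enzyme_catalogue(list(
    restriction_enzyme("CutsAll", "NNNN", cut_offset = 2),
    restriction_enzyme("Rare", "AACCGGTTAACCGGTT", cut_offset = 8),
    restriction_enzyme("RsaI", "GT^AC")
  ))
  scr <- screen_enzymes(alleles, catalogue, gel_model())
  expect_identical(scr$fraction_cut[scr$enzyme == "CutsAll"], 1)
  expect_identical(scr$fraction_cut[scr$enzyme == "Rare"], 0)
  expect_false(scr$shortlisted[scr$enzyme == "Rare"])
  expect_true(scr$shortlisted[scr$enzyme == "CutsAll"])
  # 80% threshold: an enzyme cutting 4 of 5 alleles stays shortlisted
  one_uncut <- alleles
  one_uncut[1] <- gsub("GTAC", "GTTC", one_uncut[1], fixed = TRUE)
  scr2 <- screen_enzymes(one_uncut, catalogue, gel_model())
  frac <- scr2$fraction_cut[scr2$enzyme == "RsaI"]
  if (frac == 0.8) expect_true(scr2$shortlisted[scr2$enzyme == "RsaI"])
  expect_error(screen_enzymes(alleles, list(), gel_model()), "empty")
})

test_that("minimal panel search finds a constructed two-enzyme solution", {
  # E1 confounds (a1,a2) only; E2 confounds (a3,a4) only; both needed
  e1 <- restriction_enzyme("EnzA", "G^AATTC")
  e2 <- restriction_enzyme("EnzB", "G^GATCC")
  mk <- function(e1pos, e2pos) {
    planted_seq(400, list(pos = c(e1pos, e2pos),
                          motif = c("GAATTC", "GGATCC")))
  }
  alleles <- c(a1 = mk(99, 49), a2 = mk(99, 179),
               a3 = mk(149, 119), a4 = mk(199, 119))
  cat2 <- enzyme_catalogue(list(e1, e2))
  m <- gel_model()
  rep <- min_discriminating_panels(alleles, cat2, m, max_panel_size = 2)
  expect_identical(rep$method, "exhaustive")
  expect_identical(rep$minimal_size, 2L)
  expect_identical(rep$minimal_panels, list(c("EnzA", "EnzB")))
  # single-enzyme panels each name their confounded pair
  rep1 <- min_discriminating_panels(alleles, cat2, m, max_panel_size = 1)
  expect_true(is.na(rep1$minimal_size))
  expect_identical(rep1$confounded[["EnzA"]], "a1 / a2")
  expect_identical(rep1$confounded[["EnzB"]], "a3 / a4")
})

test_that("one enzyme suffices when it separates every allele", {
  e1 <- restriction_enzyme("EnzA", "G^AATTC")
  alleles <- c(x = planted_seq(400, list(pos = 99, motif = "GAATTC")),
               y = planted_seq(400, list(pos = 149, motif = "GAATTC")),
               z = planted_seq(400, list(pos = 199, motif = "GAATTC")))
  rep <- min_discriminating_panels(alleles, enzyme_catalogue(list(e1)),
                                   gel_model(), max_panel_size = 1)
  expect_identical(rep$minimal_size, 1L)
})

test_that("exhaustive search matches brute-force subset enumeration and greedy never beats it", {
  set.seed(22)
  spec <- panel_spec(n_alleles = 6, scaffold_length = 900, sub_rate = 0.02,
                     indel_mean_events = 1, seed = 220)
  amps <- generate_panel(spec)$amplicons
  m <- gel_model()
  catalogue <- default_enzymes()
  scr <- screen_enzymes(amps, catalogue, m)
  shortlist <- catalogue[utils::head(scr$enzyme[scr$shortlisted], 8)]
  rep <- min_discriminating_panels(amps, shortlist, m, max_panel_size = 3)
  oracle <- oracle_min_panels(amps, shortlist, m, max_size = 3)
  expect_identical(rep$minimal_size, oracle$size)
  got <- lapply(rep$minimal_panels, sort)
  expect_setequal(vapply(got, paste, character(1), collapse = ","),
                  vapply(oracle$panels, paste, character(1), collapse = ","))
  # greedy (forced) finds a panel no smaller than the exhaustive minimum
  greedy <- min_discriminating_panels(amps, shortlist, m, max_panel_size = 3,
                                      exhaustive_limit = 0)
  expect_identical(greedy$method, "greedy")
  if (length(greedy$minimal_panels) > 0 && !is.na(rep$minimal_size)) {
    expect_gte(length(greedy$minimal_panels[[1]]), rep$minimal_size)
  }
})

test_that("adding an enzyme never decreases the pairs a panel separates", {
  set.seed(23)
  spec <- panel_spec(n_alleles = 5, scaffold_length = 800, seed = 230)
  amps <- generate_panel(spec)$amplicons
  m <- gel_model()
  catalogue <- default_enzymes()[c("RsaI", "MboI", "HinfI", "AluI", "TaqI")]
  bandsets <- lapply(amps, function(a) {
    lapply(catalogue, function(e) {
      suppressWarnings(observe_bands(digest_complete(a, e), m))
    })
  })
  for (k in 1:4) {
    for (trial in 1:5) {
      base <- sample(5, k)
      extra <- sample(setdiff(1:5, base), 1)
      expect_gte(oracle_pairs_distinguished(bandsets, c(base, extra), m),
                 oracle_pairs_distinguished(bandsets, base, m))
    }
  }
})

test_that("guide construction assigns ascending letters and unique codes", {
  set.seed(24)
  spec <- panel_spec(n_alleles = 5, scaffold_length = 1200, seed = 240)
  amps <- generate_panel(spec)$amplicons
  m <- gel_model()
  panel <- default_enzymes()[c("RsaI", "MboI", "HinfI")]
  rep <- min_discriminating_panels(amps, panel, m, max_panel_size = 3)
  expect_false(is.na(rep$minimal_size))
  use <- default_enzymes()[rep$minimal_panels[[1]]]
  guide <- build_guide(amps, use, m)
  expect_length(unique(guide$codes), length(amps))
  # letters of the first enzyme ascend with the pattern's largest band
  pats <- guide$patterns[[guide$panel[1]]]
  maxima <- vapply(pats, max, numeric(1))
  expect_true(all(diff(maxima) >= 0))
  # round trip: re-digesting each allele reproduces its own code
  for (id in names(amps)) {
    fp <- fingerprint(amps[[id]], use, m)
    obs <- list(individual = id, amplicon = "1",
                bands = lapply(fp, function(b) b$bands))
    expect_identical(call_allele(obs, guide, tol_bp = 0, tol_frac = 0)$allele,
                     id)
  }
  # serialisation round trip
  f <- withr::local_tempfile(fileext = ".json")
  write_guide(guide, f)
  back <- read_guide(f)
  expect_identical(back$codes, guide$codes)
  expect_equal(back$patterns, guide$patterns)
  expect_identical(back$panel, guide$panel)
})

test_that("a non-discriminating panel is rejected with the confounded pair named", {
  e1 <- restriction_enzyme("EnzA", "G^AATTC")
  twins <- c(t1 = planted_seq(300, list(pos = 99, motif = "GAATTC")),
             t2 = planted_seq(300, list(pos = 99, motif = "GAATTC")))
  expect_error(build_guide(twins, enzyme_catalogue(list(e1)), gel_model()),
               "t1 / t2")
})

test_that("the packaged capuli guide reproduces the published band data", {
  guide <- capuli_guide()
  expect_length(guide$codes, 16)
  expect_length(unique(guide$codes), 16)
  expect_identical(unname(guide$codes["S_1"]), "PJN")
  expect_equal(guide$patterns$RsaI$P, 950)
  expect_equal(guide$patterns$MboI$J, c(520, 430))
  expect_equal(guide$patterns$HinfI$N, c(550, 495))
  # fingerprinting any single-enzyme panel keeps shape: one band set each
  fp <- fingerprint(strrep("A", 500), default_enzymes()[c("RsaI")],
                    gel_model())
  expect_length(fp, 1)
  expect_equal(fp$RsaI$bands, 500)
})
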