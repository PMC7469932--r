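fixture <- load_capuli_fixture()
guide <- capuli_guide(fixture)

test_that("pattern matching finds the published letters within tolerance", {
  rsai_table <- guide$patterns$RsaI
  hinfi_table <- guide$patterns$HinfI
  expect_identical(match_pattern(950, rsai_table)$letter, "P")
  n_match <- match_pattern(c(548, 497), hinfi_table)
  expect_identical(n_match$letter, "N")            # [550, 495] within tol
  expect_identical(match_pattern(c(123, 45), rsai_table)$status, "none")
  expect_error(match_pattern(numeric(0), rsai_table), "positive")
  expect_error(match_pattern(c(100, -5), rsai_table), "positive")
})

test_that("exact ties between letters are reported as ambiguous", {
  table <- list(A = c(300, 100), B = c(310, 110))
  amb <- match_pattern(c(305, 105), table, tol_bp = 10, tol_frac = 0)
  expect_identical(amb$status, "ambiguous")
  expect_setequal(amb$candidates, c("A", "B"))
})

test_that("allele calls compose letters and look codes up in the guide", {
  obs_s1 <- list(individual = "17", amplicon = "2",
                 bands = list(RsaI = 950, MboI = c(520, 430),
                              HinfI = c(550, 495)))
  call <- call_allele(obs_s1, guide)
  expect_identical(call$code, "PJN")
  expect_identical(call$allele, "S_1")
  expect_identical(call$status, "known")

  # the first novel code after an S_18 catalogue is designated S_19
  obs_novel <- list(individual = "1", amplicon = "2",
                    bands = list(RsaI = c(280, 120, 90),
                                 MboI = c(290, 180, 100),
                                 HinfI = c(290, 220)))
  novel <- call_allele(obs_novel, guide)
  expect_identical(novel$code, "QPR")
  expect_identical(novel$status, "novel")
  expect_identical(novel$allele, "S_19")

  expect_error(call_allele(list(individual = "x", amplicon = "1",
                                bands = list(RsaI = 0, MboI = 0, HinfI = 0)),
                           guide), "positive")
  expect_error(call_allele(list(individual = "x", amplicon = "1",
                                bands = list(RsaI = 950)), guide),
               "does not cover")
})

test_that("genotype calling pairs two amplicons per individual", {
  sizes_for <- function(letters) {
    stats::setNames(lapply(seq_along(guide$panel), function(e) {
      guide$patterns[[guide$panel[e]]][[letters[e]]]
    }), guide$panel)
  }
  obs15 <- list(
    list(individual = "15", amplicon = "1", bands = sizes_for(c("K", "N", "J"))),
    list(individual = "15", amplicon = "2", bands = sizes_for(c("C", "I", "E")))
  )
  gt <- call_genotype(obs15, guide)
  expect_setequal(gt$alleles, c("S_10", "S_6"))

  # identical band sets give identical genotypes for different trees
  reg <- new_allele_registry(guide)
  gt12 <- call_genotype(lapply(obs15, function(o) {
    o$individual <- "12"; o
  }), guide, registry = reg)
  gt13 <- call_genotype(lapply(obs15, function(o) {
    o$individual <- "13"; o
  }), guide, registry = reg)
  expect_setequal(gt12$alleles, gt13$alleles)

  # homozygote mode duplicates the single call; without the flag it errors
  expect_error(call_genotype(obs15[1], guide), "homozygote")
  hom <- call_genotype(obs15[1], guide, homozygote = TRUE)
  expect_identical(hom$alleles, c("S_10", "S_10"))
  expect_error(call_genotype(c(obs15, obs15[1]), guide), "more than 2")
})

test_that("novel designations are injective and stable within a run", {
  reg <- new_allele_registry(guide)
  unknown1 <- list(individual = "a", amplicon = "1",
                   bands = list(RsaI = c(111, 99), MboI = c(333, 222),
                                HinfI = c(444)))
  unknown2 <- list(individual = "b", amplicon = "1",
                   bands = list(RsaI = c(111, 99), MboI = c(333, 222),
                                HinfI = c(444)))
  unknown3 <- list(individual = "c", amplicon = "1",
                   bands = list(RsaI = c(600, 300), MboI = c(333, 222),
                                HinfI = c(444)))
  id1 <- call_allele(unknown1, guide, reg)$allele
  id2 <- call_allele(unknown2, guide, reg)$allele
  id3 <- call_allele(unknown3, guide, reg)$allele
  expect_identical(id1, id2)        # same pattern, same designation
  expect_false(id1 == id3)          # different pattern, new designation
  expect_identical(id1, "S_19")
  expect_identical(id3, "S_20")
})

test_that("calls are stable under sub-tolerance size jitter", {
  obs <- capuli_observations(fixture)
  baseline <- call_observations(obs[, 1:4], guide)
  set.seed(31)
  for (trial in 1:5) {
    jittered <- obs
    jittered$sizes <- vapply(obs$sizes, function(s) {
      v <- as.numeric(strsplit(s, ";")[[1]])
      paste(v + stats::runif(length(v), -9.5, 9.5), collapse = ";")
    }, character(1))
    res <- call_observations(jittered[, 1:4], guide)
    expect_identical(res$genotypes$allele1, baseline$genotypes$allele1)
    expect_identical(res$genotypes$allele2, baseline$genotypes$allele2)
  }
})

test_that("the full observation table reproduces the published genotypes", {
  obs <- capuli_observations(fixture)
  res <- call_observations(obs[, 1:4], guide, tol_bp = 0, tol_frac = 0)
  expect_equal(nrow(res$genotypes), 7)
  merged <- merge(res$calls,
                  unique(obs[, c("individual", "amplicon", "expected_allele")]),
                  by.x = c("individual", "amplicon"),
                  by.y = c("individual", "amplicon"))
  expect_identical(merged$allele, merged$expected_allele)
})
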