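test_that("column entropy matches direct formula evaluation", {
  aln <- c(a = "AAB", b = "AAB", c = "ACB")
  h <- shannon_entropy_profile(aln)
  expect_equal(h[1], 0)                       # fully conserved
  expect_equal(h[3], 0)
  expect_equal(h[2], -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3))

  # 50/50 split is exactly one bit
  half <- c(a = "L", b = "L", c = "V", d = "V")
  expect_equal(shannon_entropy_profile(half)[1], 1)

  # 11 sequences split 9/1/1: H = 9/11*log2(11/9) + 2/11*log2(11)
  col <- c(rep("K", 9), "R", "T")
  aln11 <- stats::setNames(col, paste0("s", 1:11))
  expect_equal(shannon_entropy_profile(aln11)[1],
               (9 / 11) * log2(11 / 9) + (2 / 11) * log2(11),
               tolerance = 1e-12)
})

test_that("gap handling excludes gaps by default and can count them as symbols", {
  aln <- c(a = "A-", b = "C-", c = "--")
  h <- shannon_entropy_profile(aln)
  expect_equal(h[1], 1)                # gap in c excluded: A vs C, one bit
  expect_true(is.na(h[2]))             # all-gap column undefined
  expect_identical(attr(h, "flagged"), 1L)  # 0-based flagged position
  h2 <- shannon_entropy_profile(aln, gap_mode = "symbol")
  expect_equal(h2[2], 0)               # all same 'symbol'
  expect_equal(h2[1], log2(3))         # A, C, '-' uniform
})

test_that("entropy is bounded and invariant to sequence order", {
  set.seed(41)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:20) {
    n <- sample(3:12, 1)
    len <- sample(5:30, 1)
    aln <- vapply(seq_len(n), function(j) {
      paste(sample(aa, len, replace = TRUE), collapse = "")
    }, character(1))
    names(aln) <- paste0("s", seq_len(n))
    h <- shannon_entropy_profile(aln)
    expect_true(all(h >= 0 & h <= log2(20)))
    hp <- shannon_entropy_profile(aln[sample(n)])
    expect_equal(as.numeric(hp), as.numeric(h))
  }
})

test_that("region means aggregate the positional profile", {
  profile <- c(0, 0, 0, 1, 0, 1)
  regions <- data.frame(name = c("cons", "var"), start = c(0L, 2L),
                        end = c(3L, 6L))
  out <- region_mean_entropy(profile, regions)
  expect_equal(out$mean_H, c(0, 0.5))
  expect_error(region_mean_entropy(profile,
                                   data.frame(name = "bad", start = 2L,
                                              end = 2L)), "empty")
  expect_error(region_mean_entropy(profile,
                                   data.frame(name = "oob", start = 0L,
                                              end = 10L)), "bounds")
})

test_that("NG86 handles identical, synonymous-only and single-codon cases", {
  s <- "ATGCTTGAACGT"
  same <- nei_gojobori(s, s)
  expect_equal(same$ka, 0)
  expect_equal(same$ks, 0)
  expect_true(is.na(same$ka_ks))

  # 10 codons differing only by TTT<->TTC (Phe/Phe): one synonymous change
  a <- paste0("TTT", strrep("CTTGAAAGGCTG", 1), "GAACGTACCGGG", "TACCAT")
  b <- paste0("TTC", strrep("CTTGAAAGGCTG", 1), "GAACGTACCGGG", "TACCAT")
  expect_equal(nchar(a) %% 3, 0)
  r <- nei_gojobori(a, b)
  expect_equal(r$sd, 1)
  expect_equal(r$nd, 0)
  expect_equal(r$ka, 0)
  expect_gt(r$ks, 0)
  # the oracle agrees on the corrected values
  S_oracle <- sum(vapply(seq(1, nchar(a) - 2, 3), function(i) {
    (oracle_syn_sites(substr(a, i, i + 2)) +
       oracle_syn_sites(substr(b, i, i + 2))) / 2
  }, numeric(1)))
  expect_equal(r$S, S_oracle)
  expect_equal(r$ks, -0.75 * log(1 - 4 * (1 / S_oracle) / 3))

  # GTT vs GTA is Val/Val: synonymous
  v <- nei_gojobori("GTT", "GTA")
  expect_equal(v$sd, 1)
  expect_equal(v$nd, 0)
})

test_that("NG86 skips gapped codons and flags saturation", {
  r <- nei_gojobori("ATG---AAA", "ATGCCCAAA")
  expect_equal(r$n_codons_skipped, 1)
  expect_equal(r$n_codons_used, 2)
  # maximally diverged pair saturates the Jukes-Cantor correction
  sat <- nei_gojobori("TTATTATTA", "GGCGGCGGC")
  expect_true(is.na(sat$ka) || is.na(sat$ks))
  expect_identical(sat$flag, "saturated")
})

test_that("site counts and pathway averages match exhaustive enumeration", {
  set.seed(42)
  codons <- sense_codons()
  # random sample of codon pairs (the full 61 x 61 table is checked in the
  # acceptance suite)
  for (i in 1:150) {
    c1 <- sample(codons, 1)
    c2 <- sample(codons, 1)
    r <- nei_gojobori(c1, c2)
    expect_equal(r$S + r$N, 3)            # one-third rule conserves sites
    d <- oracle_ng86_diff(c1, c2)
    expect_equal(r$sd, unname(d["sd"]))
    expect_equal(r$nd, unname(d["nd"]))
    expect_equal(r$S, (oracle_syn_sites(c1) + oracle_syn_sites(c2)) / 2)
  }
})

test_that("the sliding window localises change and matches the global ratio", {
  set.seed(43)
  # identical alignment: Ka = Ks = 0, ratio undefined everywhere
  s <- paste(sample(sense_codons(), 30, replace = TRUE), collapse = "")
  aln0 <- c(a = s, b = s, c = s)
  w0 <- sliding_window_kaks(aln0, window_codons = 10)
  expect_equal(nrow(w0), 30 - 10 + 1)
  expect_true(all(w0$ka == 0))
  expect_true(all(w0$undefined))

  # one nonsynonymous change at codon 25 (0-based 24), one synonymous at 24
  base <- strsplit(s, "")[[1]]
  b <- base
  b[73:75] <- c("G", "C", "A")     # codon 25 -> GCA
  stopifnot(Biostrings::GENETIC_CODE[[paste(base[73:75], collapse = "")]] !=
              Biostrings::GENETIC_CODE[["GCA"]])
  aln <- c(a = s, b = paste(b, collapse = ""))
  w <- sliding_window_kaks(aln, window_codons = 10)
  covers <- w$start_codon <= 24 & w$end_codon > 24
  expect_true(all(w$ka[covers] > 0))
  expect_true(all(w$ka[!covers] == 0))

  # the full-length window reproduces the global pairwise aggregate
  g <- nei_gojobori_pairwise(aln)
  full <- sliding_window_kaks(aln, window_codons = 30)
  expect_equal(nrow(full), 1)
  expect_equal(full$ka, g$mean_ka)
  expect_equal(full$ks, g$mean_ks)
  if (!is.na(g$ka_ks)) expect_equal(full$ka_ks, g$ka_ks)

  expect_error(sliding_window_kaks(aln, window_codons = 31), "window longer")
})
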