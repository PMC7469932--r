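# The packaged capuli reference data: the published pattern-letter table,
# composed allele codes, the orchard genotyping observations, the crossing
# plan and the allele-catalogue provenance, all as machine-readable tables
# validated for internal consistency at load time.

read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "capsforge", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Load the capuli S-RNase CAPS reference fixture
#'
#' Returns the published capuli (Andean *Prunus serotina*) CAPS marker
#' data: the per-enzyme pattern-letter band table, the composed allele
#' codes (S_1-S_18 catalogue), the per-band observations and allele calls
#' of the 7 orchard trees (including the novel codes later designated
#' S_19-S_21), the crossing plan with expected compatibility classes, and
#' the allele-catalogue provenance table. The tables are cross-validated
#' at load: every code letter must exist in the pattern table, codes must
#' be unique, every orchard observation must resolve to its recorded
#' allele, and every expected cross class must equal the GSI model
#' prediction for the recorded genotypes. Any mismatch raises a packaging
#' error.
#'
#' @return Object of class `capuli_fixture`: list with `patterns`,
#'   `codes`, `observations`, `crosses`, `registry`, `panel` and
#'   `gel_model`.
#' @export
load_capuli_fixture <- function() {
  panel <- c("RsaI", "MboI", "HinfI")
  pat_df <- read_extdata("capuli_patterns.tsv")
  codes_df <- read_extdata("capuli_codes.tsv")
  obs_df <- read_extdata("capuli_orchard_bands.tsv")
  crosses_df <- read_extdata("capuli_crosses.tsv")
  registry_df <- read_extdata("capuli_registry.tsv")

  patterns <- lapply(panel, function(e) {
    sub <- pat_df[pat_df$enzyme == e, , drop = FALSE]
    stats::setNames(lapply(sub$sizes, function(s) {
      as.numeric(strsplit(s, ";")[[1]])
    }), sub$pattern)
  })
  names(patterns) <- panel

  codes <- stats::setNames(codes_df$code, codes_df$allele)
  fail <- function(...) stop("capuli fixture packaging error: ", ...)

  letters_per_enzyme <- lapply(patterns, names)
  if (!all(lengths(letters_per_enzyme) == lengths(letters_per_enzyme)[1])) {
    fail("pattern table letter sets differ across enzymes")
  }
  code_mat <- do.call(rbind, strsplit(codes, ""))
  for (e in seq_along(panel)) {
    used <- unique(c(code_mat[, e], obs_df[[panel[e]]]))
    missing <- setdiff(used, names(patterns[[panel[e]]]))
    if (length(missing) > 0) {
      fail("letter(s) ", paste(missing, collapse = ","),
           " missing from the ", panel[e], " pattern table")
    }
  }
  if (anyDuplicated(codes)) fail("duplicate composed codes")

  obs_df$individual <- as.character(obs_df$individual)
  obs_codes <- paste0(obs_df$RsaI, obs_df$MboI, obs_df$HinfI)
  known <- obs_df$allele %in% names(codes)
  if (!all(codes[obs_df$allele[known]] == obs_codes[known])) {
    fail("orchard observation letters disagree with the catalogue codes")
  }
  if (any(obs_codes[!known] %in% codes)) {
    fail("allele recorded as novel matches a catalogue code")
  }

  geno <- do.call(rbind, lapply(split(obs_df, obs_df$individual), function(s) {
    if (nrow(s) != 2) fail("individual ", s$individual[1],
                           " does not have exactly 2 bands")
    data.frame(individual = s$individual[1], allele1 = s$allele[1],
               allele2 = s$allele[2], stringsAsFactors = FALSE)
  }))
  rownames(geno) <- NULL
  for (i in seq_len(nrow(crosses_df))) {
    d <- geno[geno$individual == as.character(crosses_df$donor[i]), ]
    r <- geno[geno$individual == as.character(crosses_df$receptor[i]), ]
    if (nrow(d) != 1 || nrow(r) != 1) fail("cross references unknown tree")
    predicted <- classify_cross(c(d$allele1, d$allele2),
                                c(r$allele1, r$allele2))$expected_class
    if (predicted != crosses_df$expected[i]) {
      fail("expected class of cross ", crosses_df$donor[i], " x ",
           crosses_df$receptor[i], " disagrees with the GSI model")
    }
  }
  if (!all(paste0("S_", 1:21) %in% registry_df$allele)) {
    fail("allele registry incomplete")
  }

  structure(list(patterns = patterns, codes = codes,
                 observations = obs_df, crosses = crosses_df,
                 registry = registry_df, genotypes = geno,
                 panel = panel, gel_model = gel_model()),
            class = "capuli_fixture")
}

#' @export
print.capuli_fixture <- function(x, ...) {
  cat("Capuli S-RNase CAPS reference fixture\n")
  cat("  panel:", paste(x$panel, collapse = ", "), "\n")
  cat("  catalogue alleles:", length(x$codes), "; pattern letters:",
      length(x$patterns[[1]]), "per enzyme\n")
  cat("  orchard observations:", nrow(x$observations), "bands /",
      length(unique(x$observations$individual)), "trees;",
      nrow(x$crosses), "planned crosses\n")
  invisible(x)
}

#' Build a CAPS guide from the capuli fixture
#'
#' @param fixture A [load_capuli_fixture()] result (loaded if missing).
#' @param include_novel Also register the three orchard-novel codes under
#'   their designations S_19-S_21 (default `FALSE`, the catalogue as
#'   published).
#' @return A `caps_guide`.
#' @export
capuli_guide <- function(fixture = load_capuli_fixture(),
                         include_novel = FALSE) {
  codes <- fixture$codes
  if (include_novel) {
    obs <- fixture$observations
    novel <- obs[!obs$allele %in% names(codes), , drop = FALSE]
    novel_codes <- stats::setNames(
      paste0(novel$RsaI, novel$MboI, novel$HinfI), novel$allele)
    codes <- c(codes, novel_codes[!duplicated(names(novel_codes))])
  }
  enz <- tryCatch(default_enzymes()[fixture$panel], error = function(e) NULL)
  caps_guide(panel = fixture$panel, patterns = fixture$patterns,
             codes = codes, model = fixture$gel_model, enzymes = enz)
}

#' Orchard band observations with letter patterns expanded to sizes
#'
#' Expands each recorded pattern letter to its band sizes via the pattern
#' table, producing the long observation format consumed by
#' [call_observations()].
#'
#' @param fixture A [load_capuli_fixture()] result (loaded if missing).
#' @return `data.frame` with columns `individual`, `amplicon`, `enzyme`,
#'   `sizes` and `expected_allele`.
#' @export
capuli_observations <- function(fixture = load_capuli_fixture()) {
  obs <- fixture$observations
  rows <- lapply(seq_len(nrow(obs)), function(i) {
    do.call(rbind, lapply(fixture$panel, function(e) {
      letter <- obs[[e]][i]
      data.frame(individual = obs$individual[i],
                 amplicon = as.character(obs$band[i]), enzyme = e,
                 sizes = paste(fixture$patterns[[e]][[letter]],
                               collapse = ";"),
                 expected_allele = obs$allele[i],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary counts of the capuli allele catalogue
#'
#' Bookkeeping over the registry provenance table: how many distinct
#' alleles the CAPS assay resolved in the 15-accession reference panel,
#' how many of those exceed the Intron-I-resolvable set, and how many were
#' contributed by the in-vitro validation alone (no full-length sequence).
#'
#' @param fixture A [load_capuli_fixture()] result (loaded if missing).
#' @return Named list of counts: `n_accession_panel`,
#'   `n_intron1_described`, `n_beyond_intron1`, `n_in_vitro_only`,
#'   `n_orchard_novel`, `n_total_catalogue`.
#' @export
registry_summary <- function(fixture = load_capuli_fixture()) {
  reg <- fixture$registry
  list(
    n_accession_panel = sum(reg$accession_panel),
    n_intron1_described = sum(reg$intron1_described),
    n_beyond_intron1 = sum(reg$accession_panel) - sum(reg$intron1_described),
    n_in_vitro_only = sum(reg$accession_panel & !reg$full_length_sequenced),
    n_orchard_novel = sum(reg$orchard_panel & !reg$accession_panel),
    n_total_catalogue = nrow(reg)
  )
}
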