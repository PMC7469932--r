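# Seeded synthetic allele panels: a conserved scaffold carrying a
# degenerate-primer-flanked amplicon whose interior hypervariable region is
# diversified per allele by substitutions and geometric-size indels,
# emulating the length- and site-polymorphism of S-RNase C2-C3 amplicons.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic S-allele panel
#'
#' Defines the allele panel the generator emulates: a shared scaffold in
#' the amplicon size regime of S-RNase C2-C3 products (~1000-2150 bp) with
#' a hypervariable, indel-rich interior region, flanked by binding sites
#' for a degenerate primer pair.
#'
#' @param n_alleles Number of alleles, default 11.
#' @param scaffold_length Amplicon scaffold length in bp; by default drawn
#'   once (under `seed`) from 1000-2150.
#' @param var_fraction Fraction of the amplicon interior treated as the
#'   hypervariable region (default 0.5, centred).
#' @param sub_rate Per-base substitution probability inside the variable
#'   region, default 0.05.
#' @param indel_mean_events Mean number of indel events per allele
#'   (Poisson), default 3.
#' @param indel_mean_size Mean indel size in bp (geometric), default 15.
#' @param fwd,rev Degenerate primer pair to embed; defaults to the capuli
#'   C2/C3 pair Ps1C2Fw/Ps2C3Rv.
#' @param seed Mandatory integer seed.
#' @return Object of class `panel_spec`.
#' @export
panel_spec <- function(n_alleles = 11, scaffold_length = NULL,
                       var_fraction = 0.5, sub_rate = 0.05,
                       indel_mean_events = 3, indel_mean_size = 15,
                       fwd = degenerate_primer("Ps1C2Fw", "ATYCATGGCCTRTGGCCAAG"),
                       rev = degenerate_primer("Ps2C3Rv", "TGYTTRTTCCATTCVCBTTCC"),
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(n_alleles >= 1, sub_rate >= 0, sub_rate <= 1,
            var_fraction > 0, var_fraction < 1,
            indel_mean_events >= 0, indel_mean_size >= 1)
  if (is.null(scaffold_length)) {
    scaffold_length <- with_seed(seed, sample(1000:2150, 1))
  }
  stopifnot(scaffold_length >= 200)
  structure(list(n_alleles = as.integer(n_alleles),
                 scaffold_length = as.integer(scaffold_length),
                 var_fraction = var_fraction, sub_rate = sub_rate,
                 indel_mean_events = indel_mean_events,
                 indel_mean_size = indel_mean_size,
                 fwd = fwd, rev = rev, seed = as.integer(seed)),
            class = "panel_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# One concrete realisation of a degenerate motif.
instantiate_motif <- function(motif) {
  paste(vapply(strsplit(motif, "")[[1]], function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1) set else sample(set, 1)
  }, character(1)), collapse = "")
}

mutate_region <- function(region, spec) {
  chars <- strsplit(region, "")[[1]]
  hit <- stats::runif(length(chars)) < spec$sub_rate
  chars[hit] <- vapply(chars[hit], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  s <- paste(chars, collapse = "")
  n_indels <- stats::rpois(1, spec$indel_mean_events)
  for (k in seq_len(n_indels)) {
    size <- stats::rgeom(1, 1 / spec$indel_mean_size) + 1L
    if (stats::runif(1) < 0.5 || nchar(s) <= size + 10) {
      pos <- sample(nchar(s), 1)  # insertion after pos
      s <- paste0(substr(s, 1, pos), random_dna(size),
                  substr(s, pos + 1, nchar(s)))
    } else {
      pos <- sample(nchar(s) - size, 1)
      s <- paste0(substr(s, 1, pos), substr(s, pos + size + 1, nchar(s)))
    }
  }
  s
}

#' Generate a synthetic allele panel with ground truth
#'
#' All alleles share the scaffold outside the variable region; inside it,
#' per-allele substitutions and indels are applied. Primer binding sites
#' are never mutated, so amplicon extraction succeeds for every allele.
#' Pairwise distinctness is guaranteed by re-mutating colliding alleles
#' (an error is raised when distinctness is unattainable, i.e. zero
#' mutation rates with more than one allele). Output is byte-identical for
#' a fixed spec.
#'
#' @param spec A [panel_spec()].
#' @return Object of class `synthetic_panel`: list with `alleles` (named
#'   character vector, full template sequences), `amplicons` (primer-
#'   flanked products), `truth` (per allele: amplicon length and true cut
#'   sites for the capuli panel RsaI/MboI/HinfI) and the `spec`.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  if (spec$n_alleles > 1 && spec$sub_rate == 0 && spec$indel_mean_events == 0) {
    stop("distinct alleles unattainable with zero substitution and indel rates")
  }
  with_seed(spec$seed, {
    fwd_site <- instantiate_motif(spec$fwd$motif)
    rev_site <- revcomp(instantiate_motif(spec$rev$motif))
    interior_len <- spec$scaffold_length - nchar(fwd_site) - nchar(rev_site)
    var_len <- round(interior_len * spec$var_fraction)
    cons_left <- random_dna(floor((interior_len - var_len) / 2))
    cons_right <- random_dna(ceiling((interior_len - var_len) / 2))
    var_scaffold <- random_dna(var_len)
    flank5 <- random_dna(60)
    flank3 <- random_dna(60)

    alleles <- character(spec$n_alleles)
    for (i in seq_len(spec$n_alleles)) {
      attempt <- 0
      repeat {
        attempt <- attempt + 1
        var_i <- if (i == 1) var_scaffold else mutate_region(var_scaffold, spec)
        allele <- paste0(flank5, fwd_site, cons_left, var_i, cons_right,
                         rev_site, flank3)
        if (!allele %in% alleles[seq_len(i - 1)]) break
        if (attempt > 50) stop("could not generate distinct alleles")
      }
      alleles[i] <- allele
    }
    names(alleles) <- sprintf("allele_%02d", seq_len(spec$n_alleles))

    panel <- default_enzymes()[c("RsaI", "MboI", "HinfI")]
    amplicons <- vapply(names(alleles), function(id) {
      amp <- extract_amplicon(stats::setNames(alleles[id], id),
                              spec$fwd, spec$rev)
      if (amp$status == "none") stop("internal: amplification failed for ", id)
      amp$products[[1]]
    }, character(1))
    truth <- lapply(names(alleles), function(id) {
      cuts <- lapply(panel, function(e) find_cut_sites(amplicons[[id]], e))
      list(amplicon_length = nchar(amplicons[[id]]), cut_sites = cuts)
    })
    names(truth) <- names(alleles)
    structure(list(alleles = alleles, amplicons = amplicons, truth = truth,
                   spec = spec),
              class = "synthetic_panel")
  })
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("Synthetic allele panel:", length(x$alleles), "alleles, seed",
      x$spec$seed, "\n")
  cat("Amplicon lengths:", paste(nchar(x$amplicons), collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic panel to FASTA (and its truth to JSON)
#'
#' FASTA headers embed the generating specification so a panel file is
#' self-describing.
#'
#' @param panel A `synthetic_panel`.
#' @param fasta Output FASTA path (full allele templates).
#' @param truth Optional JSON path for the ground-truth record.
#' @return `fasta`, invisibly.
#' @export
write_panel <- function(panel, fasta, truth = NULL) {
  stopifnot(inherits(panel, "synthetic_panel"))
  sp <- panel$spec
  desc <- sprintf("n=%d seed=%d sub_rate=%g indel_mean=%g scaffold=%d",
                  sp$n_alleles, sp$seed, sp$sub_rate, sp$indel_mean_size,
                  sp$scaffold_length)
  seqs <- panel$alleles
  names(seqs) <- paste(names(seqs), desc)
  write_fasta(seqs, fasta)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(spec = unclass(sp[c("n_alleles", "scaffold_length", "var_fraction",
                               "sub_rate", "indel_mean_events",
                               "indel_mean_size", "seed")]),
           truth = panel$truth),
      truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(fasta)
}
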