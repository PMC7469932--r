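# In-silico PCR and complete restriction digestion: degenerate-primer
# amplicon extraction, double-strand cut-site mapping, fragment multisets
# and the gel-observation model reducing fragments to observable bands.

#' Find all matches of an IUPAC motif in a sequence
#'
#' Positions of every window of `subject` matching `motif` under IUPAC
#' set-intersection semantics (an ambiguity code in either string matches
#' when the denoted base sets intersect). Overlapping matches all count.
#'
#' @param subject Sequence (character string).
#' @param motif IUPAC motif.
#' @return Integer vector of 0-based start positions, sorted.
#' @export
find_motif_hits <- function(subject, motif) {
  subject <- toupper(subject)
  motif <- toupper(motif)
  if (nchar(motif) == 0 || nchar(motif) > nchar(subject)) return(integer(0))
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(subject),
                                fixed = FALSE)
  sort(BiocGenerics::start(m) - 1L)
}

#' Find binding sites of a degenerate primer on both strands
#'
#' Forward-strand hits are matches of the primer motif itself; reverse
#' strand hits are matches of its reverse complement (i.e. positions where
#' the primer binds the bottom strand). Positions are 0-based starts of the
#' matched window on the top strand.
#'
#' @param template Template sequence (character string).
#' @param primer A [degenerate_primer()] or a bare IUPAC motif string.
#' @return `data.frame` with columns `position` (0-based) and `strand`
#'   (`"+"`/`"-"`); zero rows when there is no hit.
#' @export
find_primer_hits <- function(template, primer) {
  motif <- primer_motif(primer)
  if (nchar(motif) >= nchar(template)) {
    stop("primer must be shorter than the template")
  }
  fwd <- find_motif_hits(template, motif)
  rev <- find_motif_hits(template, revcomp(motif))
  out <- data.frame(
    position = c(fwd, rev),
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    stringsAsFactors = FALSE
  )
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Extract PCR amplicons delimited by a degenerate primer pair
#'
#' Mimics a PCR product: the amplicon spans from the first base of a
#' forward-primer binding site to the last base of a reverse-primer binding
#' site, primers included. Each forward site is paired with the nearest
#' downstream reverse site (the shortest product, which dominates in PCR).
#' Multiple products are legitimate for heterozygous or concatenated
#' templates and are all returned with `status = "multiple"`.
#'
#' @param template Template sequence; a single named element is used for
#'   product naming.
#' @param fwd,rev Forward and reverse [degenerate_primer()]s (or motifs).
#' @return Object of class `amplification`: list with `products` (named
#'   character vector), `coords` (0-based half-open `start`/`end`), and
#'   `status` (`"none"`, `"single"` or `"multiple"`).
#' @export
extract_amplicon <- function(template, fwd, rev) {
  id <- names(template)
  if (is.null(id)) id <- "template"
  template <- toupper(template[[1]])
  fm <- primer_motif(fwd)
  rm_ <- primer_motif(rev)
  fstart <- find_motif_hits(template, fm)
  rend <- find_motif_hits(template, revcomp(rm_)) + nchar(rm_)
  pairs <- list()
  for (f in fstart) {
    cand <- rend[rend >= f + nchar(fm) + nchar(rm_)]
    if (length(cand) > 0) {
      pairs[[length(pairs) + 1L]] <- c(f, min(cand))
    }
  }
  if (length(pairs) == 0) {
    res <- structure(list(products = character(0),
                          coords = data.frame(start = integer(0),
                                              end = integer(0)),
                          status = "none"),
                     class = "amplification")
    warning("no amplification: no productive primer pair on '", id, "'")
    return(res)
  }
  coords <- unique(do.call(rbind, pairs))
  coords <- coords[order(coords[, 1], coords[, 2]), , drop = FALSE]
  products <- apply(coords, 1, function(p) {
    substr(template, p[1] + 1, p[2])
  })
  names(products) <- if (nrow(coords) == 1) id else {
    paste0(id, "_amp", seq_len(nrow(coords)))
  }
  structure(list(
    products = products,
    coords = data.frame(start = coords[, 1], end = coords[, 2]),
    status = if (nrow(coords) == 1) "single" else "multiple"
  ), class = "amplification")
}

#' @export
print.amplification <- function(x, ...) {
  cat("Amplification:", x$status, "-", length(x$products), "product(s)\n")
  if (length(x$products) > 0) {
    for (i in seq_along(x$products)) {
      cat(sprintf("  %s: [%d, %d) %d bp\n", names(x$products)[i],
                  x$coords$start[i], x$coords$end[i],
                  nchar(x$products[i])))
    }
  }
  invisible(x)
}

#' Locate double-strand cut positions of a restriction enzyme
#'
#' Every window matching the recognition motif on the top strand cuts at
#' `position + cut_offset`; a window matching only as the reverse complement
#' (bottom-strand site of a non-palindromic enzyme) cuts at
#' `position + site_length - cut_offset`, i.e. the bottom-strand offset
#' mapped back to top-strand coordinates. A window matching in both
#' orientations is one double-strand break and contributes the top-strand
#' cut only. Cuts at the very ends (yielding empty fragments) are dropped.
#'
#' @param seq Linear DNA sequence (character string).
#' @param enzyme A [restriction_enzyme()].
#' @return Sorted integer vector of between-base cut coordinates (0-based).
#' @export
find_cut_sites <- function(seq, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  seq <- toupper(seq[[1]])
  len <- nchar(seq)
  L <- nchar(enzyme$site)
  off <- enzyme$cut_offset
  top <- find_motif_hits(seq, enzyme$site)
  bottom <- find_motif_hits(seq, revcomp(enzyme$site))
  bottom_only <- setdiff(bottom, top)
  cuts <- sort(unique(c(top + off, bottom_only + (L - off))))
  cuts[cuts > 0L & cuts < len]
}

#' Complete restriction digestion of a linear sequence
#'
#' Fragments are the runs between consecutive cuts plus the two terminal
#' pieces; with `k` cuts there are `k + 1` fragments and their lengths sum
#' to the sequence length.
#'
#' @param seq Linear DNA sequence.
#' @param enzyme A [restriction_enzyme()].
#' @return Object of class `fragment_set`: list with `enzyme` and
#'   `fragments` (integer lengths, descending).
#' @export
digest_complete <- function(seq, enzyme) {
  seq <- toupper(seq[[1]])
  cuts <- find_cut_sites(seq, enzyme)
  frags <- diff(c(0L, cuts, nchar(seq)))
  structure(list(enzyme = enzyme$name,
                 fragments = sort(as.integer(frags), decreasing = TRUE)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("Digestion with", x$enzyme, ":",
      paste(x$fragments, collapse = ", "), "bp\n")
  invisible(x)
}

#' Agarose-gel observation model
#'
#' Parameters of the reduction from exact fragment lengths to what a gel
#' lane shows: fragments below `min_detectable` run off or stain too
#' weakly; fragments closer than `max(comigration_floor,
#' comigration_tol * larger)` co-migrate into one band; band sizes are read
#' off at `rounding_step` granularity. Defaults emulate a 2% agarose gel.
#'
#' @param min_detectable Minimum visible fragment size (bp), default 80.
#' @param comigration_tol Relative co-migration tolerance, default 0.05.
#' @param comigration_floor Absolute co-migration floor (bp), default 10.
#' @param rounding_step Band-size rounding step (bp), default 5.
#' @return Object of class `gel_model`.
#' @export
gel_model <- function(min_detectable = 80, comigration_tol = 0.05,
                      comigration_floor = 10, rounding_step = 5) {
  stopifnot(min_detectable >= 1, comigration_tol >= 0,
            comigration_tol < 0.5, comigration_floor >= 0,
            rounding_step >= 1)
  structure(list(min_detectable = as.numeric(min_detectable),
                 comigration_tol = as.numeric(comigration_tol),
                 comigration_floor = as.numeric(comigration_floor),
                 rounding_step = as.numeric(rounding_step)),
            class = "gel_model")
}

#' Exact (zero-tolerance) gel model
#'
#' Convenience model for purely in-silico comparisons: nothing dropped,
#' nothing merged, no rounding.
#' @return A [gel_model()].
#' @export
exact_gel_model <- function() {
  gel_model(min_detectable = 1, comigration_tol = 0,
            comigration_floor = 0, rounding_step = 1)
}

#' @export
print.gel_model <- function(x, ...) {
  cat(sprintf(
    "Gel model: detect >= %g bp, co-migration max(%g bp, %g%%), round to %g bp\n",
    x$min_detectable, x$comigration_floor, 100 * x$comigration_tol,
    x$rounding_step))
  invisible(x)
}

merge_pass <- function(sizes, model) {
  sizes <- sort(sizes, decreasing = TRUE)
  bands <- numeric(0)
  i <- 1
  while (i <= length(sizes)) {
    anchor <- sizes[i]
    j <- i
    thr <- max(model$comigration_floor, model$comigration_tol * anchor)
    while (j < length(sizes) && anchor - sizes[j + 1] <= thr) j <- j + 1
    band <- round(mean(sizes[i:j]) / model$rounding_step) * model$rounding_step
    bands <- c(bands, band)
    i <- j + 1
  }
  sort(unique(bands), decreasing = TRUE)
}

#' Reduce a fragment multiset to gel-observable bands
#'
#' Drops sub-detectable fragments, merges co-migrating fragments greedily
#' from the largest fragment downward, and rounds band sizes to the model's
#' step. Merging is iterated to a fixed point so that the operation is
#' idempotent: observing an already-observed band set changes nothing.
#'
#' @param fragments A `fragment_set` from [digest_complete()] or a numeric
#'   vector of fragment lengths.
#' @param model A [gel_model()].
#' @param enzyme Enzyme name used when `fragments` is a bare vector.
#' @return Object of class `band_set`: list with `enzyme`, `bands`
#'   (strictly descending numeric) and `empty` flag. An all-sub-detectable
#'   digest yields an empty band set with a warning.
#' @export
observe_bands <- function(fragments, model = gel_model(), enzyme = NA_character_) {
  stopifnot(inherits(model, "gel_model"))
  if (inherits(fragments, "fragment_set")) {
    enzyme <- fragments$enzyme
    sizes <- fragments$fragments
  } else if (inherits(fragments, "band_set")) {
    enzyme <- fragments$enzyme
    sizes <- fragments$bands
  } else {
    sizes <- as.numeric(fragments)
  }
  if (any(sizes <= 0)) stop("fragment lengths must be positive")
  sizes <- sizes[sizes >= model$min_detectable]
  if (length(sizes) == 0) {
    warning("no detectable bands",
            if (!is.na(enzyme)) paste0(" for enzyme ", enzyme))
    return(structure(list(enzyme = enzyme, bands = numeric(0), empty = TRUE),
                     class = "band_set"))
  }
  repeat {
    merged <- merge_pass(sizes, model)
    if (identical(merged, sizes)) break
    sizes <- merged
  }
  structure(list(enzyme = enzyme, bands = sizes, empty = FALSE),
            class = "band_set")
}

band_sizes <- function(x) {
  if (inherits(x, "band_set")) x$bands else sort(as.numeric(x), decreasing = TRUE)
}

#' @export
print.band_set <- function(x, ...) {
  cat("Bands", if (!is.na(x$enzyme)) paste0("(", x$enzyme, ")"), ":",
      if (length(x$bands)) paste(x$bands, collapse = ", ") else "<none>",
      "\n")
  invisible(x)
}
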