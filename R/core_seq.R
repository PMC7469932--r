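# Sequence, primer and enzyme data model: IUPAC semantics, FASTA and
# enzyme-catalogue I/O. Coordinates are 0-based half-open throughout the
# package; cut positions are between-base indices.

# IUPAC nucleotide codes -> set of concrete bases denoted.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_CHARS <- names(IUPAC_SETS)

#' Does an IUPAC ambiguity code match a concrete base?
#'
#' IUPAC ambiguity codes denote sets of bases (e.g. `Y` = C or T, `M` = A or
#' C, `N` = any). `iupac_matches(code, base)` is `TRUE` iff `base` belongs to
#' the set denoted by `code`. Both arguments are vectorised and recycled.
#'
#' @param code Character vector of single IUPAC nucleotide codes.
#' @param base Character vector of concrete bases (`A`, `C`, `G` or `T`).
#' @return Logical vector.
#' @examples
#' iupac_matches("Y", "C")  # TRUE
#' iupac_matches("Y", "A")  # FALSE
#' iupac_matches("N", "G")  # TRUE
#' @export
iupac_matches <- function(code, base) {
  code <- toupper(as.character(code))
  base <- toupper(as.character(base))
  if (!all(code %in% IUPAC_CHARS)) {
    stop("invalid IUPAC code(s): ",
         paste(unique(code[!code %in% IUPAC_CHARS]), collapse = ", "))
  }
  if (!all(base %in% c("A", "C", "G", "T"))) {
    stop("base must be one of A, C, G, T; got: ",
         paste(unique(base[!base %in% c("A", "C", "G", "T")]), collapse = ", "))
  }
  n <- max(length(code), length(base))
  code <- rep_len(code, n)
  base <- rep_len(base, n)
  mapply(function(co, ba) ba %in% IUPAC_SETS[[co]], code, base,
         USE.NAMES = FALSE)
}

#' Expand an IUPAC motif to a regular expression
#'
#' Each ambiguity code becomes a character class over the bases it denotes
#' (`"GANTC"` -> `"G[A][ACGT][T][C]"`-style classes). Used by the naive
#' digestion oracle and available for external tooling; the scanning
#' functions themselves use [find_motif_hits()].
#'
#' @param motif IUPAC motif string.
#' @return A regular expression string matching exactly the concrete
#'   expansions of the motif.
#' @export
iupac_to_regex <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(chars, IUPAC_CHARS)
  if (length(bad) > 0) {
    stop("invalid IUPAC character(s) in motif: ", paste(bad, collapse = ", "))
  }
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Complements ambiguity codes correctly (R<->Y, K<->M, B<->V, D<->H; S, W
#' and N are self-complementary).
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

validate_nucleotides <- function(seqs, context = "sequence") {
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    if (is.null(id) || is.na(id) || !nzchar(id)) id <- paste0("#", i)
    s <- seqs[[i]]
    if (!nzchar(s)) stop("empty sequence in record '", id, "'")
    chars <- unique(strsplit(s, "")[[1]])
    bad <- setdiff(chars, IUPAC_CHARS)
    if ("U" %in% chars) {
      stop(context, " '", id, "' contains U: RNA is not supported (DNA only)")
    }
    if (length(bad) > 0) {
      stop(context, " '", id, "' contains non-IUPAC character(s): ",
           paste(bad, collapse = ", "))
    }
  }
  invisible(seqs)
}

#' Read a (multi-)FASTA file of nucleotide sequences
#'
#' Sequences are uppercased and validated against the IUPAC nucleotide
#' alphabet; `U` (RNA) is rejected. Record ids are the first whitespace
#' delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(seqs) <- ids
  validate_nucleotides(seqs, context = "FASTA record")
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  set <- Biostrings::BStringSet(toupper(unlist(seqs)))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Degenerate PCR primer
#'
#' A named IUPAC motif, e.g. the capuli S-RNase C2-region forward primer
#' `degenerate_primer("Ps1C2Fw", "ATYCATGGCCTRTGGCCAAG")`.
#'
#' @param name Primer name.
#' @param motif IUPAC motif, length >= 10.
#' @return Object of class `degenerate_primer`.
#' @export
degenerate_primer <- function(name, motif) {
  motif <- toupper(motif)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (nchar(motif) < 10) {
    stop("primer '", name, "' is shorter than 10 nt")
  }
  bad <- setdiff(unique(strsplit(motif, "")[[1]]), IUPAC_CHARS)
  if (length(bad) > 0) {
    stop("primer '", name, "' has non-IUPAC character(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(name = name, motif = motif), class = "degenerate_primer")
}

primer_motif <- function(primer) {
  if (inherits(primer, "degenerate_primer")) primer$motif else toupper(primer)
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat("Degenerate primer", x$name, ":", x$motif,
      paste0("(", nchar(x$motif), " nt)\n"))
  invisible(x)
}

#' Restriction enzyme with an IUPAC recognition site
#'
#' The cut offset is the between-base position of the top-strand cut within
#' the recognition motif (`RsaI` = `GT^AC` has site `GTAC`, offset 2).
#'
#' @param name Enzyme name.
#' @param site Recognition site; either with an embedded `^` marking the cut
#'   (then `cut_offset` must be missing) or the bare motif.
#' @param cut_offset Integer cut position in `[0, nchar(site)]` when `site`
#'   carries no `^`.
#' @return Object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("RsaI", "GT^AC")
#' restriction_enzyme("HinfI", "GANTC", cut_offset = 1)
#' @export
restriction_enzyme <- function(name, site, cut_offset = NULL) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  site <- toupper(site)
  if (grepl("^", site, fixed = TRUE)) {
    if (!is.null(cut_offset)) {
      stop("give the cut as '^' in the site or as cut_offset, not both")
    }
    if (lengths(regmatches(site, gregexpr("\\^", site))) != 1) {
      stop("enzyme '", name, "': site must contain exactly one '^'")
    }
    cut_offset <- regexpr("^", site, fixed = TRUE)[1] - 1L
    site <- gsub("^", "", site, fixed = TRUE)
  }
  if (is.null(cut_offset)) {
    stop("enzyme '", name, "': no cut position given (use '^' or cut_offset)")
  }
  cut_offset <- as.integer(cut_offset)
  if (nchar(site) < 4) {
    stop("enzyme '", name, "': recognition site shorter than 4 nt")
  }
  bad <- setdiff(unique(strsplit(site, "")[[1]]), IUPAC_CHARS)
  if (length(bad) > 0) {
    stop("enzyme '", name, "': non-IUPAC character(s) in site: ",
         paste(bad, collapse = ", "))
  }
  if (cut_offset < 0 || cut_offset > nchar(site)) {
    stop("enzyme '", name, "': cut offset out of bounds")
  }
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  marked <- paste0(substr(x$site, 1, x$cut_offset), "^",
                   substr(x$site, x$cut_offset + 1, nchar(x$site)))
  cat("Restriction enzyme", x$name, ":", marked, "\n")
  invisible(x)
}

#' Ordered catalogue of restriction enzymes
#'
#' @param enzymes List of [restriction_enzyme()] objects with unique names.
#' @return Object of class `enzyme_catalogue` (a named list).
#' @export
enzyme_catalogue <- function(enzymes) {
  if (length(enzymes) == 0) stop("empty enzyme catalogue")
  ok <- vapply(enzymes, inherits, logical(1), "restriction_enzyme")
  if (!all(ok)) stop("all elements must be restriction_enzyme objects")
  nm <- vapply(enzymes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate enzyme name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(enzymes) <- nm
  structure(enzymes, class = "enzyme_catalogue")
}

#' @export
print.enzyme_catalogue <- function(x, ...) {
  cat("Enzyme catalogue with", length(x), "enzymes:\n")
  for (e in x) {
    marked <- paste0(substr(e$site, 1, e$cut_offset), "^",
                     substr(e$site, e$cut_offset + 1, nchar(e$site)))
    cat(sprintf("  %-10s %s\n", e$name, marked))
  }
  invisible(x)
}

#' @export
`[.enzyme_catalogue` <- function(x, i) {
  enzyme_catalogue(unclass(x)[i])
}

#' Load a restriction-enzyme catalogue from a text file
#'
#' One enzyme per line, whitespace separated: name then site with an
#' embedded `^` marking the cut (e.g. `RsaI GT^AC`). Lines starting with `#`
#' and blank lines are ignored.
#'
#' @param path Path to the catalogue file.
#' @return An [enzyme_catalogue()].
#' @seealso [default_enzymes()]
#' @export
load_enzymes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("no enzymes in ", path)
  enz <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(parts) != 2) {
      stop("malformed enzyme line (want 'name site^'): '", ln, "'")
    }
    if (!grepl("^", parts[2], fixed = TRUE)) {
      stop("enzyme '", parts[1], "': site lacks a '^' cut mark")
    }
    restriction_enzyme(parts[1], parts[2])
  })
  enzyme_catalogue(enz)
}

#' Built-in restriction-enzyme catalogue
#'
#' A curated catalogue of common commercially available enzymes, including
#' the capuli CAPS panel RsaI (`GT^AC`), MboI (`^GATC`) and HinfI
#' (`G^ANTC`). User-replaceable via [load_enzymes()].
#'
#' @return An [enzyme_catalogue()].
#' @export
default_enzymes <- function() {
  path <- system.file("extdata", "default_enzymes.txt", package = "capsforge",
                      mustWork = TRUE)
  load_enzymes(path)
}
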