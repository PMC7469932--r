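# Composite fingerprints over an enzyme panel, pattern-letter assignment,
# CAPS guide construction/serialisation and the search for minimal
# discriminating enzyme panels.

#' Digest one allele with an ordered enzyme panel
#'
#' @param allele Allele (amplicon) sequence, character string.
#' @param panel An [enzyme_catalogue()] (or list of enzymes) in panel order.
#' @param model A [gel_model()].
#' @return Named list of `band_set`s, one per enzyme, in panel order.
#' @export
fingerprint <- function(allele, panel, model = gel_model()) {
  if (length(panel) == 0) stop("empty enzyme panel")
  out <- lapply(panel, function(e) {
    suppressWarnings(observe_bands(digest_complete(allele, e), model))
  })
  names(out) <- vapply(panel, `[[`, character(1), "name")
  out
}

#' Can a gel tell two band sets apart?
#'
#' Two band sets are indistinguishable iff they have the same number of
#' bands and every size pair (compared in descending rank order) lies
#' within the model's co-migration tolerance
#' `max(comigration_floor, comigration_tol * larger)`.
#'
#' @param a,b `band_set`s (or numeric size vectors) from the same enzyme.
#' @param model A [gel_model()]; use [exact_gel_model()] for zero tolerance.
#' @return `TRUE` iff the two patterns are distinguishable.
#' @export
distinguishable <- function(a, b, model = gel_model()) {
  a <- band_sizes(a)
  b <- band_sizes(b)
  if (length(a) != length(b)) return(TRUE)
  if (length(a) == 0) return(FALSE)
  thr <- pmax(model$comigration_floor, model$comigration_tol * pmax(a, b))
  any(abs(a - b) > thr)
}

# Largest rank-wise size separation between two equal-count band sets
# (Inf when band counts differ): how robustly a gel separates them.
pattern_gap <- function(a, b) {
  a <- band_sizes(a)
  b <- band_sizes(b)
  if (length(a) != length(b)) return(Inf)
  if (length(a) == 0) return(0)
  max(abs(a - b))
}

all_fingerprints <- function(alleles, panel, model) {
  lapply(alleles, fingerprint, panel = panel, model = model)
}

#' Screen an enzyme catalogue against an allele panel
#'
#' Annotates every enzyme with the fraction of alleles it cuts (at least
#' one site) and the number of allele pairs its digestion pattern alone
#' distinguishes under the gel model. The default shortlist keeps enzymes
#' cutting at least `min_fraction` of the alleles, ranked by fraction cut
#' then by discriminated-pair count.
#'
#' @param alleles Named character vector of allele (amplicon) sequences.
#' @param catalogue An [enzyme_catalogue()].
#' @param model A [gel_model()].
#' @param min_fraction Shortlist threshold on the fraction of alleles cut,
#'   default 0.8.
#' @return `data.frame` with columns `enzyme`, `fraction_cut`,
#'   `n_pairs_distinguished`, `shortlisted`, ordered by rank.
#' @export
screen_enzymes <- function(alleles, catalogue, model = gel_model(),
                           min_fraction = 0.8) {
  if (length(catalogue) == 0) stop("empty enzyme catalogue")
  if (length(alleles) < 2) stop("need at least 2 alleles to screen")
  n <- length(alleles)
  pairs <- utils::combn(n, 2)
  rows <- lapply(catalogue, function(e) {
    digs <- lapply(alleles, function(a) {
      suppressWarnings(observe_bands(digest_complete(a, e), model))
    })
    cut <- vapply(alleles, function(a) length(find_cut_sites(a, e)) > 0,
                  logical(1))
    ndis <- sum(apply(pairs, 2, function(p) {
      distinguishable(digs[[p[1]]], digs[[p[2]]], model)
    }))
    data.frame(enzyme = e$name, fraction_cut = mean(cut),
               n_pairs_distinguished = ndis, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$shortlisted <- out$fraction_cut >= min_fraction
  out <- out[order(-out$fraction_cut, -out$n_pairs_distinguished, out$enzyme), ]
  rownames(out) <- NULL
  out
}

# Pair x enzyme distinguishability and robustness-gap matrices.
pair_matrices <- function(alleles, panel, model) {
  fps <- all_fingerprints(alleles, panel, model)
  n <- length(alleles)
  pairs <- utils::combn(n, 2)
  enames <- unname(vapply(panel, `[[`, character(1), "name"))
  D <- matrix(FALSE, ncol(pairs), length(panel),
              dimnames = list(NULL, enames))
  G <- matrix(0, ncol(pairs), length(panel), dimnames = list(NULL, enames))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    for (e in seq_along(panel)) {
      a <- fps[[i]][[e]]; b <- fps[[j]][[e]]
      D[k, e] <- distinguishable(a, b, model)
      G[k, e] <- if (D[k, e]) pattern_gap(a, b) else 0
    }
  }
  list(D = D, G = G, pairs = pairs,
       pair_labels = apply(pairs, 2, function(p) {
         paste(names(alleles)[p], collapse = " / ")
       }))
}

panel_score <- function(sel, D, G) {
  covered <- rowSums(D[, sel, drop = FALSE]) > 0
  gap <- apply(G[, sel, drop = FALSE], 1, max)
  list(n_dist = sum(covered), confounded = which(!covered),
       min_gap = if (all(covered)) min(gap) else min(gap[covered], Inf))
}

#' Search for minimal discriminating enzyme panels
#'
#' Finds the smallest enzyme subsets whose combined fingerprints tell every
#' allele pair apart under the gel model. The search is exhaustive over all
#' subsets of size `1..max_panel_size` when the shortlist has at most
#' `exhaustive_limit` enzymes, and greedy forward selection beyond that.
#' Equal-size panels are ranked by the larger minimum band-size gap across
#' their hardest allele pair (robuster gels first), then by enzyme names.
#'
#' @param alleles Named character vector of allele sequences.
#' @param shortlist An [enzyme_catalogue()] of candidate enzymes.
#' @param model A [gel_model()].
#' @param max_panel_size Largest panel size to consider.
#' @param exhaustive_limit Shortlist size up to which the subset search is
#'   exhaustive (default 15).
#' @return Object of class `discrimination_report`: list with `panels`
#'   (ranked `data.frame` of candidate panels with distinguishable-pair
#'   counts), `minimal_panels` (character vector list of all fully
#'   discriminating panels of minimal size, empty if none), `confounded`
#'   (per reported panel, the allele pairs it cannot separate), `n_pairs`,
#'   and `method` (`"exhaustive"` or `"greedy"`).
#' @export
min_discriminating_panels <- function(alleles, shortlist, model = gel_model(),
                                      max_panel_size = 3,
                                      exhaustive_limit = 15) {
  if (length(shortlist) == 0) stop("empty shortlist")
  if (length(alleles) < 2) stop("need at least 2 alleles")
  if (max_panel_size > length(shortlist)) {
    stop("max_panel_size exceeds shortlist size")
  }
  pm <- pair_matrices(alleles, shortlist, model)
  enames <- colnames(pm$D)
  npairs <- nrow(pm$D)

  rank_panels <- function(sels) {
    stats <- lapply(sels, panel_score, D = pm$D, G = pm$G)
    df <- data.frame(
      panel = vapply(sels, function(s) paste(enames[s], collapse = ","),
                     character(1)),
      size = vapply(sels, length, integer(1)),
      n_pairs_distinguished = vapply(stats, `[[`, integer(1), "n_dist"),
      n_confounded = npairs - vapply(stats, `[[`, integer(1), "n_dist"),
      min_gap = vapply(stats, `[[`, numeric(1), "min_gap"),
      stringsAsFactors = FALSE
    )
    ord <- order(-df$n_pairs_distinguished, -df$min_gap, df$panel)
    list(df = df[ord, , drop = FALSE],
         sels = sels[ord],
         stats = stats[ord])
  }

  if (length(shortlist) <= exhaustive_limit) {
    method <- "exhaustive"
    minimal <- list()
    for (size in seq_len(max_panel_size)) {
      sels <- utils::combn(length(shortlist), size, simplify = FALSE)
      full <- Filter(function(s) panel_score(s, pm$D, pm$G)$n_dist == npairs,
                     sels)
      if (length(full) > 0) {
        rk <- rank_panels(full)
        minimal <- rk$sels
        ranked <- rk
        break
      }
      if (size == max_panel_size) {
        ranked <- rank_panels(sels)
        ranked$df <- utils::head(ranked$df, 20)
        ranked$sels <- utils::head(ranked$sels, 20)
        ranked$stats <- utils::head(ranked$stats, 20)
      }
    }
  } else {
    method <- "greedy"
    sel <- integer(0)
    repeat {
      if (length(sel) == max_panel_size) break
      remaining <- setdiff(seq_along(shortlist), sel)
      gains <- vapply(remaining, function(e) {
        panel_score(c(sel, e), pm$D, pm$G)$n_dist
      }, integer(1))
      best <- remaining[order(-gains, enames[remaining])][1]
      sel <- c(sel, best)
      if (panel_score(sel, pm$D, pm$G)$n_dist == npairs) break
    }
    minimal <- if (panel_score(sel, pm$D, pm$G)$n_dist == npairs) {
      list(sort(sel))
    } else list()
    ranked <- rank_panels(list(sort(sel)))
  }

  confounded <- lapply(ranked$stats, function(s) pm$pair_labels[s$confounded])
  names(confounded) <- ranked$df$panel
  structure(list(
    panels = ranked$df,
    minimal_panels = lapply(minimal, function(s) enames[sort(s)]),
    minimal_size = if (length(minimal) > 0) length(minimal[[1]]) else NA_integer_,
    confounded = confounded,
    n_pairs = npairs,
    method = method
  ), class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat("Discrimination report (", x$method, " search, ", x$n_pairs,
      " allele pairs)\n", sep = "")
  if (length(x$minimal_panels) > 0) {
    cat("Minimal fully-discriminating panel size:", x$minimal_size, "\n")
    for (p in x$minimal_panels) cat("  {", paste(p, collapse = ", "), "}\n")
  } else {
    cat("No fully discriminating panel found; best partial panels:\n")
    print(utils::head(x$panels, 5), row.names = FALSE)
  }
  invisible(x)
}

# Letter sequence A, B, ..., Z, AA, AB, ... for pattern labelling.
pattern_letters <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  extra <- n - 26
  c(LETTERS, paste0(rep(LETTERS, each = 26, length.out = extra),
                    rep(LETTERS, times = ceiling(extra / 26))[seq_len(extra)]))
}

# Ascending lexicographic order on descending-sorted band vectors: compare
# the largest band, then the next, absent trailing bands ranking first.
order_patterns <- function(band_list) {
  if (length(band_list) <= 1) return(seq_along(band_list))
  maxlen <- max(lengths(band_list))
  keymat <- t(vapply(band_list, function(b) {
    c(b, rep(-1, maxlen - length(b)))
  }, numeric(maxlen)))
  do.call(order, as.data.frame(keymat))
}

#' Build a CAPS guide from alleles and a discriminating enzyme panel
#'
#' Digests every allele with every panel enzyme, groups indistinguishable
#' patterns, assigns pattern letters per enzyme (ascending by largest band
#' size), and composes the per-allele letter codes. Errors, listing the
#' confounded allele pairs, if the panel does not fully discriminate the
#' alleles.
#'
#' @param alleles Named character vector of allele (amplicon) sequences.
#' @param panel An [enzyme_catalogue()] in panel order.
#' @param model A [gel_model()].
#' @return Object of class `caps_guide`: list with `panel` (enzyme names),
#'   `patterns` (per enzyme, named list letter -> band sizes), `codes`
#'   (named character vector allele -> composed code), `gel_model` and the
#'   `enzymes` used.
#' @export
build_guide <- function(alleles, panel, model = gel_model()) {
  if (length(alleles) < 1) stop("no alleles")
  if (is.null(names(alleles))) stop("alleles must be named")
  fps <- all_fingerprints(alleles, panel, model)
  enames <- unname(vapply(panel, `[[`, character(1), "name"))
  patterns <- list()
  letter_of <- list()  # per enzyme: allele -> letter
  for (e in seq_along(panel)) {
    sets <- lapply(fps, function(fp) fp[[e]]$bands)
    # group alleles whose band sets a gel cannot separate (union-find by
    # transitive closure over the indistinguishability relation)
    groups <- list()
    for (i in seq_along(sets)) {
      placed <- FALSE
      for (g in seq_along(groups)) {
        if (any(vapply(groups[[g]], function(j) {
          !distinguishable(sets[[i]], sets[[j]], model)
        }, logical(1)))) {
          groups[[g]] <- c(groups[[g]], i)
          placed <- TRUE
          break
        }
      }
      if (!placed) groups[[length(groups) + 1L]] <- i
    }
    reps <- lapply(groups, function(g) sets[[g[1]]])
    ord <- order_patterns(reps)
    letters <- pattern_letters(length(groups))
    pat <- stats::setNames(reps[ord], letters)
    lo <- character(length(alleles))
    for (gi in seq_along(ord)) {
      lo[groups[[ord[gi]]]] <- letters[gi]
    }
    patterns[[enames[e]]] <- pat
    letter_of[[enames[e]]] <- stats::setNames(lo, names(alleles))
  }
  codes <- vapply(names(alleles), function(a) {
    paste(vapply(enames, function(en) letter_of[[en]][[a]], character(1)),
          collapse = "")
  }, character(1))
  dup <- codes[duplicated(codes) | duplicated(codes, fromLast = TRUE)]
  if (length(dup) > 0) {
    clash <- split(names(dup), dup)
    msg <- vapply(clash, function(m) paste(m, collapse = " / "), character(1))
    stop("panel does not discriminate all alleles; confounded: ",
         paste(msg, collapse = "; "))
  }
  structure(list(panel = enames, patterns = patterns, codes = codes,
                 gel_model = model, enzymes = panel),
            class = "caps_guide")
}

#' Assemble a CAPS guide directly from pattern and code tables
#'
#' Used to load published guides for which only band data (no sequences)
#' are available.
#'
#' @param panel Character vector of enzyme names in panel order.
#' @param patterns Per enzyme, a named list letter -> numeric band sizes.
#' @param codes Named character vector allele -> composed letter code.
#' @param model A [gel_model()].
#' @param enzymes Optional [enzyme_catalogue()] backing the panel.
#' @return A `caps_guide`.
#' @export
caps_guide <- function(panel, patterns, codes, model = gel_model(),
                       enzymes = NULL) {
  stopifnot(identical(sort(names(patterns)), sort(panel)))
  code_mat <- do.call(rbind, strsplit(codes, ""))
  if (ncol(code_mat) != length(panel)) {
    stop("codes must have one letter per panel enzyme")
  }
  for (e in seq_along(panel)) {
    missing <- setdiff(unique(code_mat[, e]), names(patterns[[panel[e]]]))
    if (length(missing) > 0) {
      stop("code letter(s) ", paste(missing, collapse = ", "),
           " undefined for enzyme ", panel[e])
    }
  }
  if (anyDuplicated(codes)) {
    stop("duplicate composed code(s): ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  }
  structure(list(panel = panel, patterns = patterns, codes = codes,
                 gel_model = model, enzymes = enzymes),
            class = "caps_guide")
}

#' @export
print.caps_guide <- function(x, ...) {
  cat("CAPS guide: panel {", paste(x$panel, collapse = ", "), "}, ",
      length(x$codes), " alleles\n", sep = "")
  letters_all <- sort(unique(unlist(lapply(x$patterns, names))))
  cat("\nPattern  ", paste(sprintf("%-22s", x$panel), collapse = ""), "\n")
  for (l in letters_all) {
    row <- vapply(x$panel, function(e) {
      b <- x$patterns[[e]][[l]]
      if (is.null(b)) "-" else paste(b, collapse = "/")
    }, character(1))
    cat(sprintf("%-8s %s\n", l, paste(sprintf("%-22s", row), collapse = "")))
  }
  cat("\nAllele codes:\n")
  for (a in names(x$codes)) cat(sprintf("  %-8s %s\n", a, x$codes[[a]]))
  invisible(x)
}

#' Serialise a CAPS guide to JSON
#'
#' Schema: `{panel, gel_model, patterns: {enzyme: {letter: [sizes]}},
#' codes: {allele: "PJN"}}`.
#'
#' @param guide A `caps_guide`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guide <- function(guide, path) {
  stopifnot(inherits(guide, "caps_guide"))
  obj <- list(
    panel = guide$panel,
    gel_model = unclass(guide$gel_model),
    patterns = lapply(guide$patterns, function(p) lapply(p, as.numeric)),
    codes = as.list(guide$codes)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a CAPS guide from JSON
#'
#' @param path Path to a guide written by [write_guide()].
#' @return A `caps_guide`.
#' @export
read_guide <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  gm <- do.call(gel_model, lapply(obj$gel_model, as.numeric))
  patterns <- lapply(obj$patterns, function(p) {
    lapply(p, function(b) as.numeric(unlist(b)))
  })
  codes <- vapply(obj$codes, as.character, character(1))
  caps_guide(panel = as.character(unlist(obj$panel)), patterns = patterns,
             codes = codes, model = gm)
}
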