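# Band-based S-allele and genotype calling against a CAPS guide, with
# tolerance matching and consistent novel-allele designation.

#' Match observed band sizes against an enzyme's pattern-letter table
#'
#' A letter matches iff its pattern has the same number of bands and every
#' size pair (descending rank order) lies within
#' `max(tol_bp, tol_frac * larger size)`. Among multiple matching letters
#' the smallest total size deviation wins; exact ties are reported as
#' ambiguous with the tied candidates.
#'
#' @param observed Numeric vector of observed band sizes (bp).
#' @param letter_table Named list letter -> pattern band sizes (one enzyme's
#'   column of the guide).
#' @param tol_bp Absolute tolerance floor (bp), default 10.
#' @param tol_frac Relative tolerance, default 0.05.
#' @return List with `status` (`"match"`, `"none"` or `"ambiguous"`),
#'   `letter` (`NA` unless `"match"`), `max_deviation`, `total_deviation`
#'   and `candidates`.
#' @export
match_pattern <- function(observed, letter_table, tol_bp = 10,
                          tol_frac = 0.05) {
  observed <- sort(as.numeric(observed), decreasing = TRUE)
  if (length(observed) == 0 || any(observed <= 0)) {
    stop("observed band sizes must be positive")
  }
  devs <- lapply(letter_table, function(pat) {
    pat <- sort(as.numeric(pat), decreasing = TRUE)
    if (length(pat) != length(observed)) return(NULL)
    d <- abs(observed - pat)
    thr <- pmax(tol_bp, tol_frac * pmax(observed, pat))
    if (any(d > thr)) return(NULL)
    d
  })
  hit <- !vapply(devs, is.null, logical(1))
  if (!any(hit)) {
    return(list(status = "none", letter = NA_character_,
                max_deviation = NA_real_, total_deviation = NA_real_,
                candidates = character(0)))
  }
  totals <- vapply(devs[hit], sum, numeric(1))
  best <- names(totals)[totals == min(totals)]
  if (length(best) > 1) {
    return(list(status = "ambiguous", letter = NA_character_,
                max_deviation = NA_real_, total_deviation = min(totals),
                candidates = best))
  }
  list(status = "match", letter = best,
       max_deviation = max(devs[[best]]), total_deviation = min(totals),
       candidates = best)
}

parse_allele_index <- function(ids) {
  m <- regmatches(ids, regexpr("[0-9]+$", ids))
  out <- rep(NA_integer_, length(ids))
  out[ids %in% regmatches(ids, regexpr(".*[0-9]+$", ids))] <-
    suppressWarnings(as.integer(m))
  out
}

#' Create a novel-allele registry for a calling session
#'
#' Tracks novel composite patterns so that the same unmatched pattern seen
#' in different individuals receives the same designation, numbered
#' `S_<next>` where `next` continues from the highest index already in the
#' guide (e.g. `S_19` after a guide ending at `S_18`).
#'
#' @param guide A `caps_guide`.
#' @return Environment of class `allele_registry`.
#' @export
new_allele_registry <- function(guide) {
  stopifnot(inherits(guide, "caps_guide"))
  idx <- parse_allele_index(names(guide$codes))
  reg <- new.env(parent = emptyenv())
  reg$next_index <- if (all(is.na(idx))) length(guide$codes) + 1L else
    max(idx, na.rm = TRUE) + 1L
  reg$novel <- list()  # signature -> designation
  class(reg) <- "allele_registry"
  reg
}

registry_designate <- function(registry, signature) {
  existing <- registry$novel[[signature]]
  if (!is.null(existing)) return(existing)
  id <- paste0("S_", registry$next_index)
  registry$next_index <- registry$next_index + 1L
  registry$novel[[signature]] <- id
  id
}

normalise_observation <- function(obs, guide) {
  stopifnot(is.list(obs), !is.null(obs$bands))
  missing <- setdiff(guide$panel, names(obs$bands))
  if (length(missing) > 0) {
    stop("observation does not cover panel enzyme(s): ",
         paste(missing, collapse = ", "))
  }
  obs$bands <- lapply(obs$bands[guide$panel], function(b) {
    b <- as.numeric(b)
    if (length(b) == 0 || any(b <= 0)) {
      stop("observed band sizes must be positive")
    }
    # symmetric with design-time gel model: ignore sub-detectable bands
    keep <- b[b >= guide$gel_model$min_detectable]
    if (length(keep) == 0) keep <- b
    sort(keep, decreasing = TRUE)
  })
  obs
}

#' Call one S-allele from a per-amplicon band observation
#'
#' Matches the observed per-enzyme band sizes to pattern letters, composes
#' the letters in panel order and looks the code up in the guide. A code
#' (or any letter) absent from the guide yields a novel designation drawn
#' from the registry; ambiguous letter matches propagate as an ambiguous
#' call listing the candidate alleles.
#'
#' @param obs List with `individual`, `amplicon` and `bands` (named list
#'   enzyme -> observed sizes covering the guide panel).
#' @param guide A `caps_guide`.
#' @param registry An [new_allele_registry()]; created ad hoc if `NULL`.
#' @param tol_bp,tol_frac Matching tolerances (see [match_pattern()]); set
#'   both to 0 for exact in-silico matching.
#' @return Object of class `allele_call`: list with `individual`,
#'   `amplicon`, `letters`, `code`, `allele`, `status` (`"known"`,
#'   `"novel"` or `"ambiguous"`), `candidates` and per-enzyme
#'   `max_deviation`.
#' @export
call_allele <- function(obs, guide, registry = NULL, tol_bp = 10,
                        tol_frac = 0.05) {
  stopifnot(inherits(guide, "caps_guide"))
  if (is.null(registry)) registry <- new_allele_registry(guide)
  obs <- normalise_observation(obs, guide)
  matches <- lapply(guide$panel, function(e) {
    match_pattern(obs$bands[[e]], guide$patterns[[e]], tol_bp, tol_frac)
  })
  names(matches) <- guide$panel
  status <- vapply(matches, `[[`, character(1), "status")
  devs <- vapply(matches, `[[`, numeric(1), "max_deviation")
  if (any(status == "ambiguous")) {
    # alleles compatible with every candidate letter set
    cand_codes <- names(guide$codes)[vapply(guide$codes, function(code) {
      ls <- strsplit(code, "")[[1]]
      all(mapply(function(l, m) l %in% m$candidates ||
                   (m$status == "match" && identical(l, m$letter)),
                 ls, matches))
    }, logical(1))]
    return(structure(list(individual = obs$individual,
                          amplicon = obs$amplicon,
                          letters = vapply(matches, `[[`, character(1), "letter"),
                          code = NA_character_, allele = NA_character_,
                          status = "ambiguous", candidates = cand_codes,
                          max_deviation = devs),
                     class = "allele_call"))
  }
  letters <- vapply(matches, `[[`, character(1), "letter")
  # signature keys the novel registry; unmatched letters are keyed by the
  # observed sizes so identical unknown patterns share a designation
  sig_parts <- mapply(function(e, m) {
    if (m$status == "match") m$letter else
      paste0("<", paste(obs$bands[[e]], collapse = ";"), ">")
  }, guide$panel, matches)
  signature <- paste(sig_parts, collapse = "|")
  code <- if (all(status == "match")) paste(letters, collapse = "") else
    NA_character_
  if (!is.na(code) && code %in% guide$codes) {
    allele <- names(guide$codes)[match(code, guide$codes)]
    st <- "known"
  } else {
    allele <- registry_designate(registry, signature)
    st <- "novel"
  }
  structure(list(individual = obs$individual, amplicon = obs$amplicon,
                 letters = letters, code = code, allele = allele,
                 status = st, candidates = allele, max_deviation = devs),
            class = "allele_call")
}

#' @export
print.allele_call <- function(x, ...) {
  cat(sprintf("Allele call [%s / %s]: %s (%s, code %s)\n",
              x$individual, x$amplicon, x$allele, x$status,
              if (is.na(x$code)) "-" else x$code))
  invisible(x)
}

#' Call an individual's S-genotype from its amplicon observations
#'
#' Heterozygote mode (the default) requires exactly two per-amplicon
#' observations; a single observation is accepted only with
#' `homozygote = TRUE` and is duplicated into a homozygous pair. More than
#' two amplicons is an error (multi-locus/tetraploid input not supported).
#'
#' @param observations List of observations (see [call_allele()]) for one
#'   individual.
#' @param guide A `caps_guide`.
#' @param registry Shared [new_allele_registry()] so novel designations are
#'   consistent across individuals.
#' @param homozygote Allow a single amplicon, called as a homozygote.
#' @param tol_bp,tol_frac Matching tolerances.
#' @return Object of class `s_genotype`: list with `individual`, `alleles`
#'   (unordered pair) and the two `calls`.
#' @export
call_genotype <- function(observations, guide, registry = NULL,
                          homozygote = FALSE, tol_bp = 10, tol_frac = 0.05) {
  if (is.null(registry)) registry <- new_allele_registry(guide)
  n <- length(observations)
  if (n > 2) stop("more than 2 amplicons per individual is not supported")
  if (n == 0) stop("no observations")
  if (n == 1 && !homozygote) {
    stop("single amplicon: use homozygote = TRUE to call a homozygote")
  }
  calls <- lapply(observations, call_allele, guide = guide,
                  registry = registry, tol_bp = tol_bp, tol_frac = tol_frac)
  if (n == 1) calls <- c(calls, calls)
  individual <- calls[[1]]$individual
  structure(list(individual = individual,
                 alleles = vapply(calls, `[[`, character(1), "allele"),
                 calls = calls),
            class = "s_genotype")
}

#' @export
print.s_genotype <- function(x, ...) {
  cat(sprintf("Individual %s: {%s, %s}\n", x$individual,
              x$alleles[1], x$alleles[2]))
  invisible(x)
}

#' Call a table of band observations
#'
#' Long-format interface matching the observations CSV: one row per
#' individual x amplicon x enzyme with semicolon-separated sizes. All
#' individuals share one registry so identical novel patterns receive the
#' same designation.
#'
#' @param obs_df `data.frame` with columns `individual`, `amplicon`,
#'   `enzyme`, `sizes` (e.g. `"520;430"`).
#' @param guide A `caps_guide`.
#' @param tol_bp,tol_frac Matching tolerances.
#' @param homozygote Allow single-amplicon individuals.
#' @return List with `calls` (`data.frame`: individual, amplicon, code,
#'   allele, status, max_deviation), `genotypes` (`data.frame`: individual,
#'   allele1, allele2) and the `registry`.
#' @export
call_observations <- function(obs_df, guide, tol_bp = 10, tol_frac = 0.05,
                              homozygote = FALSE) {
  need <- c("individual", "amplicon", "enzyme", "sizes")
  if (!all(need %in% names(obs_df))) {
    stop("observations need columns: ", paste(need, collapse = ", "))
  }
  registry <- new_allele_registry(guide)
  obs_df$individual <- as.character(obs_df$individual)
  obs_df$amplicon <- as.character(obs_df$amplicon)
  genotypes <- list()
  call_rows <- list()
  for (ind in unique(obs_df$individual)) {
    sub <- obs_df[obs_df$individual == ind, , drop = FALSE]
    obs_list <- lapply(unique(sub$amplicon), function(amp) {
      rows <- sub[sub$amplicon == amp, , drop = FALSE]
      bands <- lapply(rows$sizes, function(s) {
        as.numeric(strsplit(as.character(s), "[;,]")[[1]])
      })
      names(bands) <- rows$enzyme
      list(individual = ind, amplicon = amp, bands = bands)
    })
    gt <- call_genotype(obs_list, guide, registry = registry,
                        homozygote = homozygote,
                        tol_bp = tol_bp, tol_frac = tol_frac)
    genotypes[[ind]] <- gt
    for (cl in gt$calls[seq_along(obs_list)]) {
      call_rows[[length(call_rows) + 1L]] <- data.frame(
        individual = cl$individual, amplicon = cl$amplicon,
        code = if (is.na(cl$code)) "" else cl$code,
        allele = if (is.na(cl$allele)) "" else cl$allele,
        status = cl$status,
        max_deviation = if (all(is.na(cl$max_deviation))) NA_real_ else
          max(cl$max_deviation, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  genotype_df <- do.call(rbind, lapply(genotypes, function(g) {
    data.frame(individual = g$individual, allele1 = g$alleles[1],
               allele2 = g$alleles[2], stringsAsFactors = FALSE)
  }))
  rownames(genotype_df) <- NULL
  list(calls = do.call(rbind, call_rows), genotypes = genotype_df,
       registry = registry)
}
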