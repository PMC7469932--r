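# Independent oracles used to cross-check the implementation: a regex
# window-scanning digestion oracle, a recursive pathway-enumeration NG86
# oracle, and small generators. These deliberately share no code with the
# package internals beyond the public API they are checking.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# 0-based starts of all (overlapping) windows matching an IUPAC motif,
# found by a lookahead regex over the expanded character classes.
oracle_motif_hits <- function(seq, motif) {
  re <- iupac_to_regex(motif)
  m <- gregexpr(paste0("(?=", re, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# Naive regex-slicing digestion: top-strand windows cut at start + offset,
# windows matching only the reverse-complement motif at start + len - offset.
oracle_digest <- function(seq, enzyme) {
  L <- nchar(enzyme$site)
  top <- oracle_motif_hits(seq, enzyme$site)
  bottom <- setdiff(oracle_motif_hits(seq, revcomp(enzyme$site)), top)
  cuts <- sort(unique(c(top + enzyme$cut_offset,
                        bottom + L - enzyme$cut_offset)))
  cuts <- cuts[cuts > 0 & cuts < nchar(seq)]
  sort(diff(c(0L, cuts, nchar(seq))), decreasing = TRUE)
}

oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# Recursive enumeration of every mutational pathway between two codons:
# returns pathway-averaged (sd, nd), excluding stop-passing pathways when
# any stop-free pathway exists.
oracle_ng86_diff <- function(c1, c2) {
  paths <- list()
  recurse <- function(cur, sd, nd, stop_hit) {
    if (cur == c2) {
      paths[[length(paths) + 1L]] <<- list(sd = sd, nd = nd,
                                           stop_hit = stop_hit)
      return(invisible())
    }
    for (p in 1:3) {
      if (substr(cur, p, p) != substr(c2, p, p)) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        syn <- oracle_translate(cur) == oracle_translate(nxt) &&
          oracle_translate(cur) != "*"
        recurse(nxt, sd + as.numeric(syn), nd + as.numeric(!syn),
                stop_hit || (oracle_translate(nxt) == "*" && nxt != c2))
      }
    }
  }
  recurse(c1, 0, 0, FALSE)
  if (length(paths) == 0) return(c(sd = 0, nd = 0))
  keep <- Filter(function(p) !p$stop_hit, paths)
  if (length(keep) == 0) keep <- paths
  c(sd = mean(vapply(keep, `[[`, numeric(1), "sd")),
    nd = mean(vapply(keep, `[[`, numeric(1), "nd")))
}

# Fraction of synonymous sites of a codon by direct enumeration of the
# nine single-nucleotide mutants.
oracle_syn_sites <- function(codon) {
  aa <- oracle_translate(codon)
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (oracle_translate(mut) == aa) s <- s + 1 / 3
    }
  }
  s
}

sense_codons <- function() {
  g <- expand.grid(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"),
                   c = c("A", "C", "G", "T"), stringsAsFactors = FALSE)
  all <- paste0(g$a, g$b, g$c)
  all[vapply(all, oracle_translate, character(1)) != "*"]
}

# Number of allele pairs a panel separates, from per-enzyme observed band
# sets, used by the brute-force panel-search oracle.
oracle_pairs_distinguished <- function(bandsets, panel_idx, model) {
  n <- length(bandsets)
  pairs <- utils::combn(n, 2)
  sum(apply(pairs, 2, function(p) {
    any(vapply(panel_idx, function(e) {
      distinguishable(bandsets[[p[1]]][[e]], bandsets[[p[2]]][[e]], model)
    }, logical(1)))
  }))
}

# Exhaustive subset enumeration: smallest panel size that separates all
# pairs, and all panels of that size (as sorted name vectors).
oracle_min_panels <- function(alleles, catalogue, model, max_size) {
  bandsets <- lapply(alleles, function(a) {
    lapply(catalogue, function(e) {
      suppressWarnings(observe_bands(digest_complete(a, e), model))
    })
  })
  npairs <- choose(length(alleles), 2)
  enames <- vapply(catalogue, `[[`, character(1), "name")
  for (size in seq_len(max_size)) {
    subsets <- utils::combn(length(catalogue), size, simplify = FALSE)
    full <- Filter(function(s) {
      oracle_pairs_distinguished(bandsets, s, model) == npairs
    }, subsets)
    if (length(full) > 0) {
      return(list(size = size,
                  panels = lapply(full, function(s) sort(enames[s]))))
    }
  }
  list(size = NA_integer_, panels = list())
}

# A plain A-backbone sequence with exact motifs planted at given 0-based
# positions (for constructing alleles with known cut sites).
planted_seq <- function(len, sites) {
  s <- strrep("A", len)
  for (i in seq_along(sites$pos)) {
    substr(s, sites$pos[i] + 1,
           sites$pos[i] + nchar(sites$motif[i])) <- sites$motif[i]
  }
  s
}
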