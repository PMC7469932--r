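# Alignment variability statistics used to choose a CAPS target region:
# per-column Shannon entropy on protein alignments and Nei-Gojobori (NG86)
# Ka/Ks with Jukes-Cantor correction and a sliding window on codon
# alignments.

GAP_CHARS <- c("-", ".")

check_alignment <- function(aln) {
  if (length(aln) < 2) stop("alignment needs at least 2 sequences")
  if (length(unique(nchar(aln))) != 1) {
    stop("aligned sequences must have equal lengths")
  }
  invisible(aln)
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA (protein or nucleotide); gaps `-`.
#' @return Named character vector of equal-length uppercase sequences.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty alignment file: ", path)
  aln <- toupper(as.character(set))
  names(aln) <- sub("\\s.*$", "", names(set))
  check_alignment(aln)
  aln
}

#' Per-column Shannon entropy of an alignment
#'
#' `H(col) = -sum(p_i * log2(p_i))` over the observed symbol frequencies of
#' the column. Gap characters are excluded from the counts by default;
#' with `gap_mode = "symbol"` the gap is counted as an additional symbol.
#' All-gap columns have undefined entropy and are returned as `NA`.
#'
#' @param aln Named character vector of equal-length aligned sequences
#'   (typically protein).
#' @param gap_mode `"exclude"` (default) or `"symbol"`.
#' @return Numeric vector of per-position entropies (bits), `NA` where
#'   undefined, with attribute `"flagged"` holding the 0-based positions of
#'   undefined columns.
#' @export
shannon_entropy_profile <- function(aln, gap_mode = c("exclude", "symbol")) {
  gap_mode <- match.arg(gap_mode)
  check_alignment(aln)
  mat <- do.call(rbind, strsplit(aln, ""))
  H <- apply(mat, 2, function(col) {
    if (gap_mode == "exclude") col <- col[!col %in% GAP_CHARS]
    if (length(col) == 0) return(NA_real_)
    p <- table(col) / length(col)
    -sum(p * log2(p))
  })
  H <- as.numeric(H)
  attr(H, "flagged") <- which(is.na(H)) - 1L
  H
}

#' Mean entropy over annotated alignment regions
#'
#' @param profile Per-position entropy from [shannon_entropy_profile()].
#' @param regions `data.frame` with columns `name`, `start`, `end`
#'   (0-based, half-open, on alignment coordinates).
#' @return `data.frame` with columns `name`, `start`, `end`, `mean_H` and
#'   `n_positions` (columns with defined entropy).
#' @export
region_mean_entropy <- function(profile, regions) {
  need <- c("name", "start", "end")
  if (!all(need %in% names(regions))) {
    stop("regions need columns: ", paste(need, collapse = ", "))
  }
  n <- length(profile)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    s <- regions$start[i]; e <- regions$end[i]
    if (s < 0 || e > n || s >= e) {
      stop("region '", regions$name[i], "' [", s, ",", e,
           ") is empty or out of alignment bounds [0,", n, ")")
    }
    h <- profile[(s + 1):e]
    h <- h[!is.na(h)]
    if (length(h) == 0) stop("region '", regions$name[i],
                             "' has no defined columns")
    data.frame(name = regions$name[i], start = s, end = e,
               mean_H = mean(h), n_positions = length(h),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a BED-like region annotation file
#'
#' Three whitespace-separated columns: name, start, end (0-based,
#' half-open, alignment coordinates). `#` comment lines are ignored.
#'
#' @param path Path to the annotation file.
#' @return `data.frame` with columns `name`, `start`, `end`.
#' @export
read_regions <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("name", "start", "end"))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

# ---- NG86 machinery ---------------------------------------------------

BASES <- c("A", "C", "G", "T")

all_codons <- function() {
  g <- expand.grid(p3 = BASES, p2 = BASES, p1 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

.ng86 <- new.env(parent = emptyenv())

# Fraction of synonymous sites per codon: at each of the 3 positions, the
# share of the 3 possible nucleotide changes that preserve the amino acid.
# Changes creating a stop codon count as nonsynonymous, so S + N = 3 per
# codon exactly.
ng86_syn_sites <- function() {
  if (!is.null(.ng86$syn)) return(.ng86$syn)
  codons <- all_codons()
  syn <- vapply(codons, function(c0) {
    aa0 <- codon_aa(c0)
    if (aa0 == "*") return(NA_real_)
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(BASES, substr(c0, pos, pos))) {
        c1 <- c0
        substr(c1, pos, pos) <- b
        if (codon_aa(c1) == aa0) s <- s + 1 / 3
      }
    }
    s
  }, numeric(1))
  .ng86$syn <- syn
  syn
}

# Synonymous/nonsynonymous differences between two codons, averaged over
# all orderings of the differing positions; pathways passing through a stop
# codon are excluded (if every pathway does, all are kept with stop-passing
# steps counted as nonsynonymous).
ng86_path_diff <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  perms <- if (length(pos) == 1) list(pos) else {
    if (length(pos) == 2) list(pos, rev(pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(i) pos[i])
    }
  }
  walk <- function(order_) {
    cur <- c1
    sd <- 0; nd <- 0; stop_hit <- FALSE
    for (p in order_) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      aa_cur <- codon_aa(cur); aa_nxt <- codon_aa(nxt)
      if (aa_nxt == "*" && nxt != c2) stop_hit <- TRUE
      if (aa_cur == aa_nxt && aa_cur != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, stop_hit = stop_hit)
  }
  res <- lapply(perms, walk)
  valid <- Filter(function(r) !r$stop_hit, res)
  if (length(valid) == 0) valid <- res
  c(sd = mean(vapply(valid, `[[`, numeric(1), "sd")),
    nd = mean(vapply(valid, `[[`, numeric(1), "nd")))
}

ng86_diff_tables <- function() {
  if (!is.null(.ng86$sd)) return(list(sd = .ng86$sd, nd = .ng86$nd))
  codons <- all_codons()
  n <- length(codons)
  sd <- matrix(0, n, n, dimnames = list(codons, codons))
  nd <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        d <- ng86_path_diff(codons[i], codons[j])
        sd[i, j] <- sd[j, i] <- d[["sd"]]
        nd[i, j] <- nd[j, i] <- d[["nd"]]
      }
    }
  }
  .ng86$sd <- sd
  .ng86$nd <- nd
  list(sd = sd, nd = nd)
}

jukes_cantor <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length not divisible by 3")
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

# Per-codon NG86 components for one sequence pair; skipped codons (gap,
# ambiguity or stop in either sequence) contribute zeros and are flagged.
ng86_codon_stats <- function(a, b) {
  ca <- split_codons(toupper(a))
  cb <- split_codons(toupper(b))
  tabs <- ng86_diff_tables()
  syn <- ng86_syn_sites()
  codons <- all_codons()
  ok <- ca %in% codons & cb %in% codons &
    !is.na(syn[ca]) & !is.na(syn[cb])
  ncod <- length(ca)
  S <- Sd <- Nd <- numeric(ncod)
  S[ok] <- (syn[ca[ok]] + syn[cb[ok]]) / 2
  if (any(ok)) {
    Sd[ok] <- tabs$sd[cbind(ca[ok], cb[ok])]
    Nd[ok] <- tabs$nd[cbind(ca[ok], cb[ok])]
  }
  list(S = S, N = ifelse(ok, 3 - S, 0), sd = Sd, nd = Nd, used = ok)
}

ng86_from_sums <- function(S, N, sd, nd) {
  pS <- if (S > 0) sd / S else NA_real_
  pN <- if (N > 0) nd / N else NA_real_
  ks <- jukes_cantor(pS)
  ka <- jukes_cantor(pN)
  list(ka = ka, ks = ks,
       ka_ks = if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks,
       sd = sd, nd = nd, S = S, N = N,
       flag = if (!is.na(pS) && pS >= 0.75 || !is.na(pN) && pN >= 0.75)
         "saturated" else if (is.na(ks) || ks == 0) "ks_zero_or_undefined"
       else NA_character_)
}

#' Nei-Gojobori (1986) Ka and Ks for a codon sequence pair
#'
#' Synonymous and nonsynonymous site counts by the NG86 one-third rule,
#' differences by pathway averaging (equal weighting of mutation orderings,
#' stop-passing pathways excluded), proportions corrected with the
#' Jukes-Cantor formula `d = -3/4 * log(1 - 4p/3)`. Codons containing gaps,
#' ambiguity codes or stops in either sequence are skipped and counted.
#'
#' @param a,b In-frame nucleotide sequences of equal length (multiple of 3).
#' @return List with `ka`, `ks`, `ka_ks` (`NA` when `Ks` is 0 or
#'   undefined), difference counts `sd`, `nd`, site counts `S`, `N`,
#'   `n_codons_used`, `n_codons_skipped` and a `flag` (`"saturated"` when a
#'   proportion reaches the Jukes-Cantor limit p >= 3/4).
#' @export
nei_gojobori <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  st <- ng86_codon_stats(a, b)
  out <- ng86_from_sums(sum(st$S), sum(st$N), sum(st$sd), sum(st$nd))
  out$n_codons_used <- sum(st$used)
  out$n_codons_skipped <- sum(!st$used)
  out
}

#' Pairwise NG86 over a codon alignment
#'
#' @param aln Named character vector of equal-length in-frame sequences.
#' @return List with `pairs` (`data.frame`, one row per sequence pair) and
#'   `mean_ka`, `mean_ks`, `ka_ks` (ratio of the pairwise means, the
#'   multi-sequence aggregate also used by the sliding window).
#' @export
nei_gojobori_pairwise <- function(aln) {
  check_alignment(aln)
  n <- length(aln)
  idx <- utils::combn(n, 2)
  rows <- lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    r <- nei_gojobori(aln[[i]], aln[[j]])
    data.frame(seq1 = names(aln)[i], seq2 = names(aln)[j],
               ka = r$ka, ks = r$ks, ka_ks = r$ka_ks,
               sd = r$sd, nd = r$nd, S = r$S, N = r$N,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  mean_ka <- mean(pairs$ka, na.rm = TRUE)
  mean_ks <- mean(pairs$ks, na.rm = TRUE)
  list(pairs = pairs, mean_ka = mean_ka, mean_ks = mean_ks,
       ka_ks = if (is.na(mean_ks) || mean_ks == 0) NA_real_ else
         mean_ka / mean_ks)
}

#' Sliding-window Ka/Ks profile of a codon alignment
#'
#' For every window of `window_codons` codons (stepping `step_codons`),
#' Ka and Ks are computed per sequence pair from the window's NG86 site and
#' difference sums, averaged over pairs, and their ratio reported. Windows
#' where the mean Ks is zero or undefined are flagged `undefined` rather
#' than infinite.
#'
#' @param aln Named character vector of equal-length in-frame sequences.
#' @param window_codons Window length in codons (default 20).
#' @param step_codons Step in codons (default 1).
#' @return `data.frame` with columns `start_codon` (0-based), `end_codon`,
#'   `ka`, `ks`, `ka_ks` and `undefined`.
#' @export
sliding_window_kaks <- function(aln, window_codons = 20, step_codons = 1) {
  check_alignment(aln)
  n_codons <- nchar(aln[[1]]) / 3
  if (n_codons != floor(n_codons)) stop("alignment length not divisible by 3")
  if (window_codons > n_codons) {
    stop("window longer than the alignment (", n_codons, " codons)")
  }
  n <- length(aln)
  idx <- utils::combn(n, 2)
  stats <- lapply(seq_len(ncol(idx)), function(k) {
    ng86_codon_stats(aln[[idx[1, k]]], aln[[idx[2, k]]])
  })
  starts <- seq(0, n_codons - window_codons, by = step_codons)
  csum <- function(v) c(0, cumsum(v))
  cums <- lapply(stats, function(st) {
    list(S = csum(st$S), N = csum(st$N), sd = csum(st$sd), nd = csum(st$nd))
  })
  rows <- lapply(starts, function(s) {
    e <- s + window_codons
    ka <- ks <- numeric(0)
    for (cs in cums) {
      r <- ng86_from_sums(cs$S[e + 1] - cs$S[s + 1],
                          cs$N[e + 1] - cs$N[s + 1],
                          cs$sd[e + 1] - cs$sd[s + 1],
                          cs$nd[e + 1] - cs$nd[s + 1])
      ka <- c(ka, r$ka)
      ks <- c(ks, r$ks)
    }
    mka <- mean(ka, na.rm = TRUE)
    mks <- mean(ks, na.rm = TRUE)
    undef <- is.na(mks) || is.nan(mks) || mks == 0 || is.nan(mka)
    data.frame(start_codon = s, end_codon = e,
               ka = if (is.nan(mka)) NA_real_ else mka,
               ks = if (is.nan(mks)) NA_real_ else mks,
               ka_ks = if (undef) NA_real_ else mka / mks,
               undefined = undef)
  })
  do.call(rbind, rows)
}
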