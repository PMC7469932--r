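# Gametophytic self-incompatibility (GSI) cross classification: a pollen
# haplotype carrying an S-allele present in the pistil pair is rejected in
# the style, so the fraction of accepted pollen haplotypes is 0, 1/2 or 1.

cross_classes <- c("incompatible", "semi_compatible", "compatible")

check_genotype_pair <- function(g, who) {
  if (inherits(g, "s_genotype")) g <- g$alleles
  g <- as.character(g)
  if (length(g) != 2) stop(who, " genotype must carry exactly two alleles")
  if (any(is.na(g)) || any(!nzchar(g)) || any(g == "?")) {
    stop("classification refused: unresolved allele in ", who, " genotype")
  }
  g
}

#' Classify a cross under gametophytic self-incompatibility
#'
#' Each pollen haplotype (one donor allele) is rejected iff that allele
#' occurs in the receptor (pistil) pair. Zero accepted haplotypes gives an
#' incompatible cross, one of two semi-compatible, both compatible.
#'
#' @param donor,receptor S-genotypes: character vectors of two allele ids
#'   or `s_genotype` objects from [call_genotype()].
#' @return Object of class `cross_plan`: list with `donor`, `receptor`,
#'   `expected_class` and `compatible_pollen_fraction` (0, 0.5 or 1).
#' @export
classify_cross <- function(donor, receptor) {
  d <- check_genotype_pair(donor, "donor")
  r <- check_genotype_pair(receptor, "receptor")
  accepted <- !(d %in% r)
  frac <- mean(accepted)
  cls <- cross_classes[1 + 2 * frac]
  structure(list(donor = d, receptor = r, expected_class = cls,
                 compatible_pollen_fraction = frac),
            class = "cross_plan")
}

#' @export
print.cross_plan <- function(x, ...) {
  cat(sprintf("Cross (%s,%s) x (%s,%s): %s (pollen fraction %.1f)\n",
              x$donor[1], x$donor[2], x$receptor[1], x$receptor[2],
              x$expected_class, x$compatible_pollen_fraction))
  invisible(x)
}

genotype_frame <- function(genotypes) {
  if (is.data.frame(genotypes)) {
    need <- c("individual", "allele1", "allele2")
    if (!all(need %in% names(genotypes))) {
      stop("genotype table needs columns: ", paste(need, collapse = ", "))
    }
    return(genotypes)
  }
  do.call(rbind, lapply(genotypes, function(g) {
    data.frame(individual = g$individual, allele1 = g$alleles[1],
               allele2 = g$alleles[2], stringsAsFactors = FALSE)
  }))
}

#' Partition individuals into incompatibility groups
#'
#' Individuals sharing an identical unordered S-allele pair belong to the
#' same incompatibility group (IG) and are mutually cross-incompatible.
#'
#' @param genotypes `data.frame` with columns `individual`, `allele1`,
#'   `allele2`, or a list of `s_genotype`s.
#' @param include_singletons Report single-member groups too (default
#'   `FALSE`).
#' @return `data.frame` with columns `group`, `alleles` and `members`
#'   (comma-separated individual ids).
#' @export
incompatibility_groups <- function(genotypes, include_singletons = FALSE) {
  df <- genotype_frame(genotypes)
  key <- vapply(seq_len(nrow(df)), function(i) {
    paste(sort(c(df$allele1[i], df$allele2[i])), collapse = ",")
  }, character(1))
  groups <- split(df$individual, key)
  if (!include_singletons) groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0) {
    return(data.frame(group = character(0), alleles = character(0),
                      members = character(0), stringsAsFactors = FALSE))
  }
  groups <- groups[order(names(groups))]
  data.frame(
    group = paste0("IG", seq_along(groups)),
    alleles = names(groups),
    members = vapply(groups, function(m) {
      paste(as.character(m), collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Expected-compatibility matrix for all ordered crosses
#'
#' Rows are pollen donors, columns pollen receptors; the diagonal holds
#' selfings, which are always incompatible for heterozygotes under GSI.
#'
#' @param genotypes As in [incompatibility_groups()].
#' @return Character matrix of expected classes with individual ids as
#'   dimnames.
#' @export
cross_matrix <- function(genotypes) {
  df <- genotype_frame(genotypes)
  if (nrow(df) < 1) stop("need at least one genotype")
  n <- nrow(df)
  ids <- as.character(df$individual)
  m <- matrix(NA_character_, n, n, dimnames = list(donor = ids,
                                                   receptor = ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- classify_cross(c(df$allele1[i], df$allele2[i]),
                                c(df$allele1[j], df$allele2[j]))$expected_class
    }
  }
  m
}
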