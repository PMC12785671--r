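#' Estimate per-locus allele frequencies
#'
#' Frequencies are simple allele counts over non-missing calls:
#' `p_a = count(a) / (2 * n_scored)`. Missing calls are excluded from the
#' denominator (per-locus pairwise deletion). The returned object also
#' records, per locus, the number of scored samples, which downstream
#' estimators use when folding extra reference individuals into the
#' frequency estimate.
#'
#' @param table A [genotype_table].
#' @param exclude Optional character vector of sample ids to leave out of
#'   the counts (e.g. a focal dyad).
#' @return An `allele_freq_table`: a named list (one element per locus) of
#'   named numeric vectors (allele length -> frequency), each with an
#'   `n_obs` attribute giving the number of scored samples.
#' @export
allele_frequencies <- function(table, exclude = NULL) {
  keep <- !(table$samples$sample %in% exclude)
  out <- lapply(seq_len(ncol(table$a)), function(l) {
    al <- c(table$a[keep, l], table$b[keep, l])
    al <- al[!is.na(al)]
    if (length(al) == 0)
      stop("locus '", table$loci$locus[l], "' has no scored calls")
    tab <- table(al)
    p <- as.numeric(tab) / length(al)
    names(p) <- names(tab)
    attr(p, "n_obs") <- length(al) / 2
    p
  })
  names(out) <- table$loci$locus
  structure(out, class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat("allele_freq_table:", length(x), "loci;",
      "alleles per locus:", paste(range(lengths(x)), collapse = "-"), "\n")
  invisible(x)
}

# Frequency lookup for a vector of alleles at one locus; errors on alleles
# absent from the table unless a floor frequency is supplied (then the
# allele is injected at `floor` and the rest rescaled).
freq_lookup <- function(p, alleles, floor = NULL) {
  key <- as.character(alleles)
  hit <- match(key, names(p))
  if (anyNA(hit)) {
    if (is.null(floor))
      stop("allele ", key[is.na(hit)][1], " absent from frequency table")
    miss <- unique(key[is.na(hit)])
    padd <- rep(floor, length(miss))
    names(padd) <- miss
    p2 <- c(as.numeric(p) * (1 - sum(padd)), padd)
    names(p2) <- c(names(p), miss)
    return(freq_lookup(p2, alleles))
  }
  as.numeric(p[hit])
}

# Fold one extra individual's genotypes into an allele-frequency table.
# Used by the triadic relatedness mode: each reference individual's alleles
# are added to the per-locus counts, p' = (2N p + n_ref_allele)/(2N + 2).
augment_freqs <- function(freqs, geno) {
  out <- lapply(seq_along(freqs), function(l) {
    p <- freqs[[l]]
    g <- geno[l, ]
    if (anyNA(g)) return(p)
    n2 <- 2 * attr(p, "n_obs")
    cnt <- as.numeric(p) * n2
    names(cnt) <- names(p)
    for (al in as.character(g)) {
      if (al %in% names(cnt)) cnt[al] <- cnt[al] + 1 else {
        cnt <- c(cnt, stats::setNames(1, al))
      }
    }
    p2 <- cnt / (n2 + 2)
    attr(p2, "n_obs") <- attr(p, "n_obs") + 1
    p2
  })
  names(out) <- names(freqs)
  structure(out, class = "allele_freq_table")
}
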