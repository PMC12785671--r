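#' Codominant genetic distance matrix
#'
#' Per-locus squared genetic distance for codominant data: each genotype is
#' encoded as a vector of allele counts `x` (entries 0/1/2) and the locus
#' distance is `0.5 * sum((x - y)^2)`, which takes the familiar values
#' 0 (identical genotypes), 1 (one shared allele), 2 (two heterozygotes
#' sharing none), 3 (homozygote vs heterozygote sharing none) or 4
#' (different homozygotes). Loci where either sample is missing are dropped
#' for that pair (pairwise deletion); the total distance is the sum over
#' scored loci, optionally rescaled by `n_loci / n_scored`.
#'
#' @param table A [genotype_table] with at least two samples.
#' @param rescale_missing If `TRUE`, each pair's distance is scaled by the
#'   ratio of total loci to loci actually scored for that pair.
#' @return Symmetric numeric matrix with sample ids as dimnames.
#' @export
codominant_distance <- function(table, rescale_missing = FALSE) {
  n <- n_samples(table)
  if (n < 2) stop("need at least two samples")
  L <- n_loci(table)
  a <- table$a; b <- table$b
  d <- matrix(0, n, n, dimnames = list(table$samples$sample, table$samples$sample))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(a[i, ]) & !is.na(a[j, ])
      if (!any(ok))
        stop("samples '", table$samples$sample[i], "' and '",
             table$samples$sample[j], "' share no scored locus")
      dl <- locus_sq_distance(a[i, ok], b[i, ok], a[j, ok], b[j, ok])
      tot <- sum(dl)
      if (rescale_missing) tot <- tot * L / sum(ok)
      d[i, j] <- d[j, i] <- tot
    }
  }
  d
}

# Vectorised per-locus squared distance between two genotype series.
locus_sq_distance <- function(a1, b1, a2, b2) {
  hom1 <- a1 == b1
  hom2 <- a2 == b2
  shared <- (a1 == a2) + (a1 == b2) + (b1 == a2) + (b1 == b2)
  same <- a1 == a2 & b1 == b2
  out <- numeric(length(a1))
  # both homozygous
  m <- hom1 & hom2
  out[m] <- ifelse(same[m], 0, 4)
  # one homozygous, one heterozygous
  m <- xor(hom1, hom2)
  out[m] <- ifelse(shared[m] > 0, 1, 3)
  # both heterozygous
  m <- !hom1 & !hom2
  out[m] <- ifelse(same[m], 0, ifelse(shared[m] > 0, 1, 2))
  out
}

validate_dist <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (any(!is.finite(d))) stop("distance matrix must be finite")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
  d
}
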