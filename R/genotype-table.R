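#' Construct a diploid codominant genotype table
#'
#' The central data container: a set of samples genotyped at a set of
#' codominant loci (microsatellites or indels), each call being two allele
#' fragment lengths in base pairs. Missing calls are `NA` for both alleles;
#' a call can never be half-missing. Within each call the two alleles are
#' stored in canonical (non-decreasing) order so genotype equality does not
#' depend on input order.
#'
#' @param a,b Integer matrices (samples x loci) of allele lengths in bp;
#'   `NA` marks missing. Entries are reordered so that `a <= b` elementwise.
#' @param samples Data frame with columns `sample` (unique ids), and
#'   optionally `population` and `si_group` (self-incompatibility group,
#'   `"G1"`/`"G2"`, or `NA`).
#' @param loci Data frame with columns `locus` (unique names), and optionally
#'   `marker_class` (`"neutral_ssr"` or `"functional"`) and `motif_step`
#'   (repeat-motif length in bp, default 2).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(a, b, samples, loci) {
  a <- as.matrix(a); b <- as.matrix(b)
  storage.mode(a) <- "integer"; storage.mode(b) <- "integer"
  if (!all(dim(a) == dim(b))) stop("allele matrices must have equal dimensions")
  if (is.character(samples)) samples <- data.frame(sample = samples)
  if (is.character(loci)) loci <- data.frame(locus = loci)
  samples <- as.data.frame(samples); loci <- as.data.frame(loci)
  if (!"population" %in% names(samples)) samples$population <- NA_character_
  if (!"si_group" %in% names(samples)) samples$si_group <- NA_character_
  if (!"marker_class" %in% names(loci)) loci$marker_class <- "neutral_ssr"
  if (!"motif_step" %in% names(loci)) loci$motif_step <- 2L
  if (nrow(samples) != nrow(a)) stop("sample metadata does not match matrix rows")
  if (nrow(loci) != ncol(a)) stop("locus metadata does not match matrix columns")
  if (anyDuplicated(samples$sample)) {
    dup <- samples$sample[duplicated(samples$sample)][1]
    stop("duplicate sample id: ", dup)
  }
  if (anyDuplicated(loci$locus)) stop("duplicate locus name")
  if (any(loci$motif_step < 1)) stop("motif_step must be >= 1")
  half <- xor(is.na(a), is.na(b))
  if (any(half)) {
    idx <- which(half, arr.ind = TRUE)[1, ]
    stop("single-allele call for sample '", samples$sample[idx[1]],
         "' at locus '", loci$locus[idx[2]], "': both alleles must be present or both missing")
  }
  if (any(a <= 0, na.rm = TRUE) || any(b <= 0, na.rm = TRUE))
    stop("allele sizes must be positive")
  swap <- !is.na(a) & a > b
  if (any(swap)) {
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  dimnames(a) <- dimnames(b) <- list(samples$sample, loci$locus)
  structure(list(samples = samples, loci = loci, a = a, b = b),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$a), "samples x", ncol(x$a), "loci\n")
  miss <- mean(is.na(x$a))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  nsi <- sum(!is.na(x$samples$si_group))
  if (nsi > 0) cat("  SI groups labelled for", nsi, "samples\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$a)

#' Number of samples / loci in a genotype table
#' @param table A `genotype_table`.
#' @return Integer count.
#' @export
n_samples <- function(table) nrow(table$a)

#' @rdname n_samples
#' @export
n_loci <- function(table) ncol(table$a)

#' Subset a genotype table
#'
#' @param table A `genotype_table`.
#' @param samples,loci Indices, logical masks, or names selecting rows /
#'   columns. Either may repeat entries (used by locus bootstrapping).
#' @return A `genotype_table`. Repeated loci get unique suffixed names.
#' @export
subset_table <- function(table, samples = NULL, loci = NULL) {
  si <- samples %||% seq_len(nrow(table$a))
  li <- loci %||% seq_len(ncol(table$a))
  if (is.character(si)) si <- match(si, table$samples$sample)
  if (is.character(li)) li <- match(li, table$loci$locus)
  if (anyNA(si)) stop("unknown sample id")
  if (anyNA(li)) stop("unknown locus name")
  smp <- table$samples[si, , drop = FALSE]
  loc <- table$loci[li, , drop = FALSE]
  if (anyDuplicated(loc$locus)) loc$locus <- make.unique(loc$locus)
  genotype_table(table$a[si, li, drop = FALSE], table$b[si, li, drop = FALSE],
                 smp, loc)
}

#' Extract one sample's genotypes as a 2-column matrix
#'
#' @param table A `genotype_table`.
#' @param sample A sample id or row index.
#' @return Integer matrix (loci x 2) with rownames = locus names.
#' @export
sample_genotypes <- function(table, sample) {
  i <- if (is.character(sample)) match(sample, table$samples$sample) else sample
  if (is.na(i)) stop("unknown sample id: ", sample)
  m <- cbind(a = table$a[i, ], b = table$b[i, ])
  rownames(m) <- table$loci$locus
  m
}

genotype_equal <- function(x, y) {
  identical(x$samples$sample, y$samples$sample) &&
    identical(x$loci$locus, y$loci$locus) &&
    identical(unname(x$a), unname(y$a)) &&
    identical(unname(x$b), unname(y$b))
}
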