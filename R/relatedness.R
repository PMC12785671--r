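#' Pairwise relatedness estimators for codominant genotypes
#'
#' Relatedness `r` is parameterised through the IBD coefficients
#' `(k0, k1, k2)` — the probabilities that a non-inbred dyad shares 0, 1 or
#' 2 alleles identical by descent at a locus — with `r = k1/2 + k2`.
#' Three estimators are provided:
#'
#' * `moment_r()`: the Queller-Goodnight ratio-of-sums moment estimator,
#'   symmetrised by averaging the two reference orientations. It is
#'   unbiased but unbounded, so estimates may fall outside `[0, 1]`; such
#'   estimates are returned untruncated with a `truncated = FALSE` flag.
#' * `dyadic_ml_r()`: maximum likelihood over the `(k0, k1, k2)` simplex
#'   (no-inbreeding model), maximising the summed log of
#'   [dyad_likelihood()] across loci by a dense simplex grid search
#'   (step 0.01) followed by Nelder-Mead refinement. `r` lies in `[0, 1]`
#'   by construction.
#' * `triadic_ml_r()`: a reference-individual mode in the spirit of
#'   triadic-likelihood (TrioML) estimation: for each of `n_refs` randomly
#'   drawn reference individuals, the reference's alleles are folded into
#'   the allele-frequency estimate and the dyadic ML fit repeated; the
#'   per-reference estimates are combined by a likelihood-weighted mean.
#'   An entirely missing reference leaves the frequencies untouched, so the
#'   mode reduces exactly to `dyadic_ml_r()` in that case.
#'
#' @param g1,g2 Genotype series for the two individuals: integer matrices
#'   (loci x 2) as returned by [sample_genotypes()].
#' @param freqs An `allele_freq_table` from [allele_frequencies()].
#' @param floor Optional floor frequency used to inject alleles absent from
#'   `freqs`; by default such alleles are an error.
#' @return A `relatedness_estimate`: list with `r`, `estimator`,
#'   `loci_used`, and for likelihood estimators the fitted `k` vector
#'   `(k0, k1, k2)`.
#' @export
moment_r <- function(g1, g2, freqs, floor = NULL) {
  sh <- shared_loci(g1, g2, freqs)
  if (length(sh) == 0) stop("no shared scored loci")
  t12 <- qg_terms(g1, g2, freqs, sh, floor)
  t21 <- qg_terms(g2, g1, freqs, sh, floor)
  if (abs(sum(t12$den)) < 1e-12 || abs(sum(t21$den)) < 1e-12)
    stop("moment estimator undefined: no informative (polymorphic) overlap")
  r <- (sum(t12$num) / sum(t12$den) + sum(t21$num) / sum(t21$den)) / 2
  new_rel_estimate(r, "moment", loci_used = length(sh),
                   truncated = FALSE, out_of_range = (r < 0 || r > 1))
}

shared_loci <- function(g1, g2, freqs) {
  which(!is.na(g1[, 1]) & !is.na(g2[, 1]))
}

# Queller-Goodnight per-locus numerator/denominator with g1 as reference.
qg_terms <- function(g1, g2, freqs, sh, floor = NULL) {
  num <- den <- numeric(length(sh))
  for (idx in seq_along(sh)) {
    l <- sh[idx]
    p <- freqs[[l]]
    a <- g1[l, 1]; b <- g1[l, 2]
    c_ <- g2[l, 1]; d <- g2[l, 2]
    pa <- freq_lookup(p, a, floor); pb <- freq_lookup(p, b, floor)
    s <- 0.5 * ((a == c_) + (a == d) + (b == c_) + (b == d))
    num[idx] <- s - pa - pb
    den[idx] <- 1 + (a == b) - pa - pb
  }
  list(num = num, den = den)
}

#' Likelihood of a genotype pair given IBD coefficients
#'
#' The single-locus likelihood kernel used by the ML estimators:
#' `P = k2*P2 + k1*P1 + k0*P0`, where `P0 = P(g1) P(g2)` (independence),
#' `P2 = P(g1)` when the genotypes are identical (else 0), and `P1` covers
#' the one-shared-IBD-allele configurations: `(ii,ii) -> p_i^3`,
#' `(ii,ij) -> p_i^2 p_j`, `(ij,ij) -> p_i p_j (p_i + p_j)`,
#' `(ij,ik) -> p_i p_j p_k`, otherwise 0. Genotype probabilities follow
#' Hardy-Weinberg: `P(ii) = p_i^2`, `P(ij) = 2 p_i p_j`. Summed over all
#' ordered genotype pairs the kernel integrates to 1 for any `k` on the
#' simplex.
#'
#' @param g1,g2 Length-2 integer vectors (one genotype each, any order).
#' @param k Numeric vector `(k0, k1, k2)` on the probability simplex.
#' @param p Named numeric vector of allele frequencies at the locus.
#' @param floor Optional floor frequency for alleles absent from `p`.
#' @return The likelihood (a single probability).
#' @export
dyad_likelihood <- function(g1, g2, k, p, floor = NULL) {
  if (anyNA(g1) || anyNA(g2)) stop("calls must be non-missing")
  if (abs(sum(k) - 1) > 1e-6 || any(k < -1e-12))
    stop("k must lie on the probability simplex")
  comp <- locus_components(sort(g1), sort(g2), p, floor)
  sum(k[3] * comp[1], k[2] * comp[2], k[1] * comp[3])
}

# (P2, P1, P0) for one locus; genotypes must be in canonical order.
locus_components <- function(g1, g2, p, floor = NULL) {
  a <- g1[1]; b <- g1[2]; c_ <- g2[1]; d <- g2[2]
  pr <- freq_lookup(p, c(a, b, c_, d), floor)
  pa <- pr[1]; pb <- pr[2]; pc <- pr[3]; pd <- pr[4]
  pg <- function(x, y, px, py) if (x == y) px * px else 2 * px * py
  P0 <- pg(a, b, pa, pb) * pg(c_, d, pc, pd)
  same <- (a == c_ && b == d)
  P2 <- if (same) pg(a, b, pa, pb) else 0
  hom1 <- a == b; hom2 <- c_ == d
  P1 <- if (hom1 && hom2) {
    if (a == c_) pa^3 else 0
  } else if (hom1) {                      # (ii, jk)
    if (a == c_) pa^2 * pd else if (a == d) pa^2 * pc else 0
  } else if (hom2) {                      # (jk, ii)
    if (c_ == a) pc^2 * pb else if (c_ == b) pc^2 * pa else 0
  } else if (same) {                      # (ij, ij)
    pa * pb * (pa + pb)
  } else {                                # two distinct heterozygotes
    if (a == c_) pa * pb * pd
    else if (a == d) pa * pb * pc
    else if (b == c_) pb * pa * pd
    else if (b == d) pb * pa * pc
    else 0
  }
  c(P2 = P2, P1 = P1, P0 = P0)
}

# Per-locus component matrix (L x 3: P2, P1, P0) over shared loci.
component_matrix <- function(g1, g2, freqs, floor = NULL) {
  sh <- shared_loci(g1, g2, freqs)
  if (length(sh) == 0) stop("no shared scored loci")
  M <- t(vapply(sh, function(l)
    locus_components(g1[l, ], g2[l, ], freqs[[l]], floor), numeric(3)))
  rownames(M) <- names(freqs)[sh]
  M
}

# Dense simplex grid (k2, k1, k0) at the given step.
k_grid <- function(step = 0.01) {
  k2 <- seq(0, 1, by = step)
  g <- do.call(rbind, lapply(k2, function(x)
    cbind(k2 = x, k1 = seq(0, 1 - x + 1e-12, by = step))))
  g[, 2] <- pmin(g[, 2], 1 - g[, 1])
  cbind(g, k0 = pmax(0, 1 - g[, 1] - g[, 2]))
}

.grid_cache <- new.env(parent = emptyenv())
k_grid_cached <- function(step = 0.01) {
  key <- as.character(step)
  if (is.null(.grid_cache[[key]])) .grid_cache[[key]] <- k_grid(step)
  .grid_cache[[key]]
}

# Fit (k0,k1,k2) by grid search + optional Nelder-Mead refinement.
# M: L x 3 matrix of (P2, P1, P0).
fit_dyadic_ml <- function(M, step = 0.01, refine = TRUE, tol = 1e-8) {
  informative <- apply(M, 1, function(x) diff(range(x)) > 1e-15)
  if (!any(informative))
    stop("all shared loci are uninformative (monomorphic): likelihood is flat")
  Mi <- M[informative, , drop = FALSE]
  G <- k_grid_cached(step)                       # columns k2, k1, k0
  ll <- colSums(log(pmax(Mi %*% t(G), 1e-300)))
  best <- which.max(ll)
  k <- c(k0 = G[best, 3], k1 = G[best, 2], k2 = G[best, 1])
  best_ll <- ll[best]
  if (refine) {
    negll <- function(th) {
      e <- exp(c(0, th))
      kk <- e / sum(e)                           # (k0, k1, k2)
      -sum(log(pmax(Mi %*% rev(kk), 1e-300)))
    }
    start <- log(pmax(k[2:3], 1e-8) / max(k[1], 1e-8))
    opt <- stats::optim(start, negll, method = "Nelder-Mead",
                        control = list(reltol = tol, maxit = 500))
    if (-opt$value > best_ll) {
      e <- exp(c(0, opt$par))
      k <- e / sum(e)
      names(k) <- c("k0", "k1", "k2")
      best_ll <- -opt$value
    }
  }
  list(k = k, r = unname(k[2] / 2 + k[3]), loglik = best_ll,
       loci_used = nrow(M))
}

#' @rdname moment_r
#' @param step Grid step for the simplex search.
#' @param refine Refine the grid optimum by Nelder-Mead.
#' @export
dyadic_ml_r <- function(g1, g2, freqs, floor = NULL, step = 0.01,
                        refine = TRUE) {
  M <- component_matrix(g1, g2, freqs, floor)
  fit <- fit_dyadic_ml(M, step, refine)
  new_rel_estimate(fit$r, "dyadic_ml", loci_used = fit$loci_used, k = fit$k,
                   loglik = fit$loglik)
}

#' @rdname moment_r
#' @param reference_panel List of genotype series (loci x 2 matrices) to
#'   draw reference individuals from.
#' @param n_refs Number of reference individuals to draw (without
#'   replacement; capped at the panel size with a warning).
#' @param seed Integer seed for the reference-draw stream.
#' @export
triadic_ml_r <- function(g1, g2, reference_panel, freqs, n_refs = 100,
                         seed = 1, floor = NULL, step = 0.01,
                         refine = FALSE) {
  if (length(reference_panel) == 0) {
    warning("empty reference panel: falling back to dyadic ML")
    return(dyadic_ml_r(g1, g2, freqs, floor, step, refine = TRUE))
  }
  if (n_refs > length(reference_panel)) {
    warning("n_refs exceeds panel size; capped at ", length(reference_panel))
    n_refs <- length(reference_panel)
  }
  take <- with_stream(seed, "triadic_refs",
                      sample.int(length(reference_panel), n_refs))
  rs <- numeric(n_refs); lls <- numeric(n_refs)
  loci_used <- NA_integer_
  for (i in seq_len(n_refs)) {
    fr <- augment_freqs(freqs, reference_panel[[take[i]]])
    M <- component_matrix(g1, g2, fr, floor)
    fit <- fit_dyadic_ml(M, step, refine)
    rs[i] <- fit$r; lls[i] <- fit$loglik; loci_used <- fit$loci_used
  }
  w <- exp(lls - max(lls))
  r <- sum(w * rs) / sum(w)
  new_rel_estimate(min(max(r, 0), 1), "triadic_ml", loci_used = loci_used,
                   n_refs = n_refs)
}

new_rel_estimate <- function(r, estimator, loci_used, k = NULL, ci = NULL,
                             loglik = NULL, n_refs = NULL, truncated = NULL,
                             out_of_range = FALSE) {
  structure(list(r = r, estimator = estimator, loci_used = loci_used,
                 k = k, ci_low = ci[1] %||% NA_real_,
                 ci_high = ci[2] %||% NA_real_, loglik = loglik,
                 n_refs = n_refs, out_of_range = out_of_range),
            class = "relatedness_estimate")
}

#' @export
print.relatedness_estimate <- function(x, ...) {
  cat(sprintf("relatedness (%s): r = %.4f over %d loci\n", x$estimator, x$r,
              x$loci_used))
  if (!is.na(x$ci_low))
    cat(sprintf("  %s CI: [%.4f, %.4f]\n", "bootstrap", x$ci_low, x$ci_high))
  if (!is.null(x$k))
    cat(sprintf("  k = (%.3f, %.3f, %.3f)\n", x$k[1], x$k[2], x$k[3]))
  invisible(x)
}

#' Locus-bootstrap confidence interval for a relatedness estimate
#'
#' Resamples loci with replacement, re-estimates `r` for each replicate and
#' returns the percentile interval at the requested level.
#'
#' @inheritParams moment_r
#' @param estimator `"moment"`, `"dyadic_ml"` or `"triadic_ml"`.
#' @param reps Number of bootstrap replicates.
#' @param level Interval coverage (default 0.95).
#' @param seed Integer seed for the bootstrap stream.
#' @param ... Passed to the estimator (`reference_panel`, `n_refs`, ...).
#' @return The point estimate with `ci_low`/`ci_high` filled in.
#' @export
bootstrap_ci <- function(estimator = c("moment", "dyadic_ml", "triadic_ml"),
                         g1, g2, freqs, reps = 1000, level = 0.95, seed = 1,
                         floor = NULL, ...) {
  estimator <- match.arg(estimator)
  sh <- shared_loci(g1, g2, freqs)
  if (length(sh) < 2) stop("locus bootstrap needs at least 2 shared loci")
  dots <- list(...)
  panel <- dots$reference_panel
  est_fun <- function(gg1, gg2, fr, idx = NULL) {
    switch(estimator,
           moment = moment_r(gg1, gg2, fr, floor),
           dyadic_ml = dyadic_ml_r(gg1, gg2, fr, floor, refine = FALSE),
           triadic_ml = {
             pan <- if (is.null(idx)) panel else
               lapply(panel, function(g) g[idx, , drop = FALSE])
             triadic_ml_r(gg1, gg2, reference_panel = pan, freqs = fr,
                          n_refs = dots$n_refs %||% 100, seed = seed,
                          floor = floor)
           })
  }
  point <- est_fun(g1, g2, freqs)
  reps_r <- with_stream(seed, "ci_bootstrap", {
    vapply(seq_len(reps), function(b) {
      idx <- sample(sh, length(sh), replace = TRUE)
      fr <- freqs[idx]
      names(fr) <- sprintf("L%d", seq_along(idx))
      class(fr) <- "allele_freq_table"
      gg1 <- g1[idx, , drop = FALSE]; gg2 <- g2[idx, , drop = FALSE]
      est_fun(gg1, gg2, fr, idx)$r
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(reps_r, c(alpha, 1 - alpha), type = 7))
  point$ci_low <- ci[1]; point$ci_high <- ci[2]
  point
}

#' All-dyads relatedness matrix
#'
#' Estimates `r` for every unordered pair of samples. Per-dyad estimation
#' failures (e.g. no informative overlap) are recorded as missing estimates
#' with a reason, not propagated as errors.
#'
#' @param table A [genotype_table] with at least two samples.
#' @param estimator `"moment"`, `"dyadic_ml"` or `"triadic_ml"`.
#' @param freqs Optional precomputed `allele_freq_table`; by default
#'   frequencies are estimated from the full table (including each focal
#'   dyad). Set `exclude_focal = TRUE` to re-estimate per dyad without the
#'   two focal individuals.
#' @param exclude_focal Exclude the focal dyad from frequency estimation.
#' @param n_refs,seed Triadic-mode settings (see [triadic_ml_r()]).
#' @param floor Optional floor frequency for unseen alleles.
#' @return A `relatedness_matrix`: list with `ids`, the symmetric numeric
#'   matrix `r` (diagonal `NA`), the `estimator`, and a long-format data
#'   frame `dyads` with one row per unordered pair.
#' @export
relatedness_matrix <- function(table,
                               estimator = c("moment", "dyadic_ml", "triadic_ml"),
                               freqs = NULL, exclude_focal = FALSE,
                               n_refs = 100, seed = 1, floor = NULL) {
  estimator <- match.arg(estimator)
  n <- n_samples(table)
  if (n < 2) stop("need at least two samples")
  ids <- table$samples$sample
  if (is.null(freqs)) freqs <- allele_frequencies(table)
  genos <- lapply(seq_len(n), function(i) cbind(table$a[i, ], table$b[i, ]))
  rmat <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  pairs <- utils::combn(n, 2)
  nd <- ncol(pairs)
  out <- data.frame(id1 = character(nd), id2 = character(nd),
                    estimator = estimator, r = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, loci_used = NA_integer_,
                    note = NA_character_, stringsAsFactors = FALSE)
  for (d in seq_len(nd)) {
    i <- pairs[1, d]; j <- pairs[2, d]
    o <- sort(c(ids[i], ids[j]))
    out$id1[d] <- o[1]; out$id2[d] <- o[2]
    fr <- if (exclude_focal)
      allele_frequencies(table, exclude = c(ids[i], ids[j])) else freqs
    est <- tryCatch(
      switch(estimator,
             moment = moment_r(genos[[i]], genos[[j]], fr, floor),
             dyadic_ml = dyadic_ml_r(genos[[i]], genos[[j]], fr, floor),
             triadic_ml = triadic_ml_r(genos[[i]], genos[[j]],
                                       reference_panel = genos[-c(i, j)],
                                       freqs = fr, n_refs = n_refs,
                                       seed = stream_seed(seed, paste0("dyad", d)),
                                       floor = floor)),
      error = function(e) e)
    if (inherits(est, "error")) {
      out$note[d] <- conditionMessage(est)
    } else {
      out$r[d] <- est$r
      out$loci_used[d] <- est$loci_used
      rmat[i, j] <- rmat[j, i] <- est$r
    }
  }
  structure(list(ids = ids, r = rmat, estimator = estimator, dyads = out),
            class = "relatedness_matrix")
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  cat("relatedness_matrix (", x$estimator, "): ", length(x$ids),
      " samples, ", nrow(x$dyads), " dyads\n", sep = "")
  fail <- sum(!is.na(x$dyads$note))
  if (fail) cat("  ", fail, " dyads without estimate\n", sep = "")
  invisible(x)
}
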