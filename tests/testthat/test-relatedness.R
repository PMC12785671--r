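freqs_from <- function(...) {
  fr <- lapply(list(...), function(p) {
    attr(p, "n_obs") <- 100
    p
  })
  names(fr) <- paste0("L", seq_along(fr))
  class(fr) <- "allele_freq_table"
  fr
}

test_that("dyad likelihood reproduces the closed-form limits", {
  p <- setNames(c(0.5, 0.3, 0.2), c("100", "102", "104"))
  pg <- function(g) hwe_prob(g, p)
  g1 <- c(100, 102); g2 <- c(100, 104)
  expect_equal(dyad_likelihood(g1, g2, c(1, 0, 0), p), pg(g1) * pg(g2))
  expect_equal(dyad_likelihood(g1, g1, c(0, 0, 1), p), 2 * 0.5 * 0.3)
  # homozygote vs sharing heterozygote under k = (0,1,0): p_i^2 p_j
  expect_equal(dyad_likelihood(c(100, 100), c(100, 102), c(0, 1, 0),
                               setNames(c(0.5, 0.5), c("100", "102"))),
               0.125)
  expect_error(dyad_likelihood(g1, g2, c(0.5, 0.5, 0.5), p), "simplex")
  expect_error(dyad_likelihood(g1, c(100, 999), c(1, 0, 0), p), "absent")
})

test_that("dyad likelihood sums to 1 over all ordered genotype pairs", {
  set.seed(5)
  for (rep in 1:5) {
    w <- rgamma(3, 1); p <- setNames(w / sum(w), c("10", "12", "14"))
    kw <- rgamma(3, 1); k <- kw / sum(kw)
    gts <- all_genotypes(c(10, 12, 14))
    tot <- 0
    for (g1 in gts) for (g2 in gts)
      tot <- tot + dyad_likelihood(g1, g2, k, p)
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("moment estimator is near 1 for clones and near 0 for unrelated pairs", {
  # clones: identical heterozygotes with rare alleles at every locus
  p <- setNames(c(0.01, 0.01, 0.98), c("100", "102", "200"))
  fr <- freqs_from(p, p, p, p)
  g <- matrix(rep(c(100, 102), 4), 4, 2, byrow = TRUE)
  est <- moment_r(g, g, fr)
  expect_gt(est$r, 0.95)
  expect_equal(est$loci_used, 4)
  # unrelated: two genotypes drawn independently from the frequencies
  set.seed(8)
  L <- 10000
  pu <- setNames(rep(0.2, 5), as.character(seq(100, 108, 2)))
  fru <- do.call(freqs_from, rep(list(pu), L))
  draw <- function() matrix(sample(seq(100, 108, 2), 2 * L, replace = TRUE), L, 2)
  est0 <- moment_r(draw(), draw(), fru)
  expect_lt(abs(est0$r), 0.02)
  # monomorphic-only overlap leaves the ratio undefined
  mono <- freqs_from(setNames(1, "100"))
  gm <- matrix(c(100, 100), 1, 2)
  expect_error(moment_r(gm, gm, mono), "undefined")
})

test_that("dyadic ML recovers clones and unrelated dyads and is optimal", {
  set.seed(9)
  L <- 100
  alleles <- seq(100, 118, 2)
  p <- setNames(rep(0.1, 10), as.character(alleles))
  fr <- do.call(freqs_from, rep(list(p), L))
  gclone <- matrix(sample(alleles, 2 * L, replace = TRUE), L, 2)
  expect_gte(dyadic_ml_r(gclone, gclone, fr)$r, 0.95)
  runr <- replicate(40, {
    dyadic_ml_r(matrix(sample(alleles, 2 * L, TRUE), L, 2),
                matrix(sample(alleles, 2 * L, TRUE), L, 2), fr)$r
  })
  expect_lte(median(runr), 0.05)
  # fitted maximum beats the three simplex vertices
  g1 <- matrix(sample(alleles, 2 * L, TRUE), L, 2)
  g2 <- matrix(sample(alleles, 2 * L, TRUE), L, 2)
  fit <- dyadic_ml_r(g1, g2, fr)
  ll_at <- function(k) sum(log(mapply(function(l)
    dyad_likelihood(g1[l, ], g2[l, ], k, fr[[l]]), seq_len(L))))
  expect_gte(fit$loglik + 1e-6, ll_at(c(1, 0, 0)))
  expect_gte(fit$loglik + 1e-6, ll_at(c(0, 1, 0)))
  expect_gte(fit$loglik + 1e-6, ll_at(c(0, 0, 1)))
  expect_equal(sum(fit$k), 1, tolerance = 1e-9)
  expect_true(all(fit$k >= 0) && fit$r >= 0 && fit$r <= 1)
  expect_error(dyadic_ml_r(matrix(c(100, 100), 1, 2), matrix(c(100, 100), 1, 2),
                           freqs_from(setNames(1, "100"))), "monomorphic")
})

test_that("estimates are invariant to allele relabelling and locus order", {
  set.seed(10)
  L <- 20
  alleles <- seq(100, 110, 2)
  p <- setNames(c(0.3, 0.25, 0.2, 0.1, 0.1, 0.05), as.character(alleles))
  fr <- do.call(freqs_from, rep(list(p), L))
  g1 <- matrix(sample(alleles, 2 * L, TRUE, prob = p), L, 2)
  g2 <- matrix(sample(alleles, 2 * L, TRUE, prob = p), L, 2)
  base_m <- moment_r(g1, g2, fr)$r
  base_d <- dyadic_ml_r(g1, g2, fr)$r
  # relabel alleles by an order-preserving shift of 1000 bp
  shift <- function(m) m + 1000
  fr2 <- lapply(fr, function(pp) {
    names(pp) <- as.character(as.integer(names(pp)) + 1000)
    pp
  })
  class(fr2) <- "allele_freq_table"
  expect_equal(moment_r(shift(g1), shift(g2), fr2)$r, base_m)
  expect_equal(dyadic_ml_r(shift(g1), shift(g2), fr2)$r, base_d)
  # permute loci
  perm <- sample(L)
  frp <- fr[perm]; class(frp) <- "allele_freq_table"
  expect_equal(moment_r(g1[perm, ], g2[perm, ], frp)$r, base_m)
  expect_equal(dyadic_ml_r(g1[perm, ], g2[perm, ], frp)$r, base_d)
})

test_that("triadic mode reduces to dyadic ML with uninformative references", {
  set.seed(11)
  L <- 12
  alleles <- seq(100, 110, 2)
  p <- setNames(rep(1 / 6, 6), as.character(alleles))
  fr <- do.call(freqs_from, rep(list(p), L))
  g1 <- matrix(sample(alleles, 2 * L, TRUE), L, 2)
  g2 <- matrix(sample(alleles, 2 * L, TRUE), L, 2)
  blank <- matrix(NA_integer_, L, 2)
  tri <- triadic_ml_r(g1, g2, list(blank, blank, blank), fr, n_refs = 3)
  dy <- dyadic_ml_r(g1, g2, fr, refine = FALSE)
  expect_equal(tri$r, dy$r, tolerance = 1e-9)
  expect_warning(triadic_ml_r(g1, g2, list(blank), fr, n_refs = 5), "capped")
  expect_warning(triadic_ml_r(g1, g2, list(), fr), "empty reference panel")
})

test_that("triadic estimates of parent-offspring dyads centre on 0.5", {
  po <- benchmark_po_recovery(n_dyads = 60, panel_founders = 60,
                              estimator = "triadic_ml", n_refs = 30, seed = 13)
  expect_lt(abs(mean(po$r_hat) - 0.5), 0.05)
  expect_true(all(po$r_hat >= 0 & po$r_hat <= 1))
})

test_that("locus-bootstrap intervals behave at the degenerate and trivial limits", {
  # clones scored at 8 copies of the same locus pattern: zero resampling
  # variance, degenerate interval
  p <- setNames(c(0.1, 0.1, 0.8), c("100", "102", "200"))
  fr <- do.call(freqs_from, rep(list(p), 8))
  g <- matrix(rep(c(100, 102), 8), 8, 2, byrow = TRUE)
  ci <- bootstrap_ci("dyadic_ml", g, g, fr, reps = 50, seed = 2)
  expect_lte(ci$ci_high - ci$ci_low, 0.01)
  expect_true(ci$ci_low <= ci$r && ci$r <= ci$ci_high)
  # reps = 1: both bounds equal the single replicate
  ci1 <- bootstrap_ci("moment", g, g, fr, reps = 1, seed = 2)
  expect_equal(ci1$ci_low, ci1$ci_high)
  expect_error(bootstrap_ci("moment", g[1, , drop = FALSE],
                            g[1, , drop = FALSE], fr[1]), "at least 2")
})

test_that("bootstrap intervals usually cover the point estimate", {
  set.seed(14)
  cfg <- sim_config(n_loci = 12, alleles_per_locus = c(6, 10), seed = 31,
                    mutation_rate = 0)
  sim <- simulate_dataset(cfg, "trios_panel", n_trios = 3, n_extra = 10)
  fr <- allele_frequencies(sim$table)
  cover <- vapply(1:3, function(k) {
    g1 <- sample_genotypes(sim$table, sprintf("F%03d", 2 * k - 1))
    g2 <- sample_genotypes(sim$table, sprintf("O%03d", k))
    ci <- bootstrap_ci("dyadic_ml", g1, g2, fr, reps = 200, seed = k)
    ci$ci_low <= ci$r + 1e-9 && ci$r <= ci$ci_high + 1e-9
  }, logical(1))
  expect_true(all(cover))
})

test_that("the dyad matrix enumerates all unordered pairs and records failures", {
  tab <- fixture_table()
  rm2 <- relatedness_matrix(subset_table(tab, samples = 1:2), "moment")
  expect_equal(nrow(rm2$dyads), 1)
  rmat <- relatedness_matrix(tab, "dyadic_ml")
  expect_equal(nrow(rmat$dyads), choose(4, 2))
  expect_equal(rmat$r["Frantoio", "Don Carlo"], rmat$r["Don Carlo", "Frantoio"])
  # a sample with no scorable overlap yields a recorded reason, not an error
  tabm <- make_table(list(rbind(c(1, 2), c(1, 2), c(NA, NA)),
                          rbind(c(3, 4), c(3, 3), c(NA, NA))),
                     samples = c("A", "B", "C"))
  rmm <- relatedness_matrix(tabm, "moment")
  expect_true(any(!is.na(rmm$dyads$note)))
  expect_true(all(is.na(rmm$r["C", c("A", "B")])))
})

test_that("the 24-individual mixed panel is estimated with small error at 50 loci", {
  cfg <- sim_config(n_loci = 50, alleles_per_locus = c(6, 10), seed = 17,
                    mutation_rate = 0)
  sim <- simulate_dataset(cfg, "mixed_kinship_panel")
  rmat <- relatedness_matrix(sim$table, "dyadic_ml")
  merged <- merge(rmat$dyads, sim$truth, by = c("id1", "id2"))
  expect_equal(nrow(merged), nrow(sim$truth))
  expect_lte(mean(abs(merged$r - merged$r_true)), 0.08)
})
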