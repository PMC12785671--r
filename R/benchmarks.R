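#' Parameter-recovery benchmarks for the relatedness estimators
#'
#' `benchmark_po_recovery()` simulates independent parent-offspring dyads,
#' each embedded in a panel of unrelated founders, and estimates each dyad
#' with the likelihood estimator using allele frequencies computed from the
#' whole panel (the published per-dyad r-values of any particular cultivar
#' collection depend on its unpublished genotype matrix; recovering the
#' canonical expectation r = 0.5 across simulated dyads is the matching
#' validation). Defaults mirror a 12-locus SSR panel: Dirichlet(1) allele
#' frequencies over 6-10 alleles per locus, no mutation, no genotyping
#' error, 100 founders per panel.
#'
#' `benchmark_kin_recovery()` estimates dyads of known relatedness
#' (unrelated 0, first cousins 0.125, half sibs 0.25, parent-offspring
#' 0.5) simulated inside founder panels at a configurable locus count, for
#' bias assessment.
#'
#' @param n_dyads Number of independent parent-offspring dyads.
#' @param panel_founders Unrelated founders per panel (the parent pair is
#'   part of the founder set).
#' @param n_loci,n_alleles Locus count and per-locus allele-count range.
#' @param estimator `"dyadic_ml"`, `"triadic_ml"` or `"moment"`.
#' @param n_refs Reference draws for the triadic mode.
#' @param seed Master seed; each dyad derives its own stream.
#' @return `benchmark_po_recovery()`: data frame with one row per dyad
#'   (`dyad`, `r_hat`).
#' @export
benchmark_po_recovery <- function(n_dyads = 500, panel_founders = 100,
                                  n_loci = 12, n_alleles = c(6, 10),
                                  estimator = c("dyadic_ml", "triadic_ml",
                                                "moment"),
                                  n_refs = 100, seed = 1) {
  estimator <- match.arg(estimator)
  r_hat <- vapply(seq_len(n_dyads), function(d) {
    cfg <- sim_config(n_loci = n_loci, alleles_per_locus = n_alleles,
                      dirichlet_alpha = 1, mutation_rate = 0, error_rate = 0,
                      seed = stream_seed(seed, paste0("po_dyad", d)))
    ped <- build_trios_panel(cfg, n_trios = 1, n_extra = panel_founders - 2)
    fou <- simulate_founders(cfg, sum(is_founder(ped)),
                             ids = ped$id[is_founder(ped)],
                             si_groups = group_of(ped$si_genotype[is_founder(ped)]))
    tab <- drop_alleles(ped, fou$table, cfg)
    freqs <- allele_frequencies(tab)
    gm <- sample_genotypes(tab, "F001")
    go <- sample_genotypes(tab, "O001")
    est <- switch(estimator,
                  dyadic_ml = dyadic_ml_r(gm, go, freqs),
                  moment = moment_r(gm, go, freqs),
                  triadic_ml = {
                    others <- setdiff(tab$samples$sample, c("F001", "O001"))
                    panel <- lapply(others, function(s) sample_genotypes(tab, s))
                    triadic_ml_r(gm, go, panel, freqs, n_refs = n_refs,
                                 seed = stream_seed(seed, paste0("refs", d)))
                  })
    est$r
  }, numeric(1))
  data.frame(dyad = seq_len(n_dyads), r_hat = r_hat)
}

#' @rdname benchmark_po_recovery
#' @param pairs_per_class Dyads per relatedness class.
#' @param n_panels Number of independent panels the pairs are spread over.
#' @export
benchmark_kin_recovery <- function(pairs_per_class = 100, n_panels = 10,
                                   n_loci = 100, n_alleles = 10,
                                   estimator = c("dyadic_ml", "moment"),
                                   seed = 1) {
  estimator <- match.arg(estimator)
  per <- ceiling(pairs_per_class / n_panels)
  out <- list()
  for (pn in seq_len(n_panels)) {
    cfg <- sim_config(n_loci = n_loci, alleles_per_locus = n_alleles,
                      dirichlet_alpha = 1, mutation_rate = 0, error_rate = 0,
                      seed = stream_seed(seed, paste0("kin_panel", pn)))
    built <- build_kin_pairs_pedigree(cfg, per)
    ped <- built$ped
    fou <- simulate_founders(cfg, sum(is_founder(ped)),
                             ids = ped$id[is_founder(ped)],
                             si_groups = group_of(ped$si_genotype[is_founder(ped)]))
    tab <- drop_alleles(ped, fou$table, cfg)
    freqs <- allele_frequencies(tab)
    for (k in seq_len(nrow(built$pairs))) {
      g1 <- sample_genotypes(tab, built$pairs$id1[k])
      g2 <- sample_genotypes(tab, built$pairs$id2[k])
      est <- switch(estimator,
                    dyadic_ml = dyadic_ml_r(g1, g2, freqs),
                    moment = moment_r(g1, g2, freqs))
      out[[length(out) + 1]] <- data.frame(panel = pn,
                                           r_true = built$pairs$r_true[k],
                                           class = built$pairs$class[k],
                                           r_hat = est$r)
    }
  }
  do.call(rbind, out)
}

# Pedigree with `per` dyads each of true r 0, 0.125, 0.25 and 0.5, all
# parents drawn from a founder pool laid out with alternating SI groups.
build_kin_pairs_pedigree <- function(cfg, per) {
  # worst-case per iteration: 6 G1 founders (mothers + possible G1 mates)
  # and 7 G2 founders (fathers, half-sib co-parents, possible G2 mates)
  nG1 <- per * 6 + 4; nG2 <- per * 7 + 4
  nf <- nG1 + nG2
  si <- c(rep("S1S2", nG1), rep("S1S1", nG2))
  fids <- sprintf("F%03d", seq_len(nf))
  e <- new.env()
  e$si <- si; e$fids <- fids; e$pool <- seq_len(nf); e$used <- rep(FALSE, nf)
  take <- function(group) {
    i <- which(group_of(e$si[e$pool]) == group & !e$used[e$pool])[1]
    stopifnot(!is.na(i))
    idx <- e$pool[i]; e$used[idx] <- TRUE
    list(id = fids[idx], si = si[idx])
  }
  rows <- founder_rows(fids, si)
  pairs <- list()
  with_stream(cfg$seed, "si", {
    for (k in seq_len(per)) {
      # parent-offspring
      m <- take("G1"); f <- take("G2")
      id <- sprintf("PO%03d", k)
      rows <- rbind(rows, child_row(id, m$id, f$id, draw_si_child(m$si, f$si)))
      pairs[[length(pairs) + 1]] <- data.frame(id1 = m$id, id2 = id,
                                               r_true = 0.5, class = "parent_offspring")
      # half sibs (shared mother)
      a <- take("G1"); b <- take("G2"); c_ <- take("G2")
      h1 <- sprintf("HS%03da", k); h2 <- sprintf("HS%03db", k)
      rows <- rbind(rows,
                    child_row(h1, a$id, b$id, draw_si_child(a$si, b$si)),
                    child_row(h2, a$id, c_$id, draw_si_child(a$si, c_$si)))
      pairs[[length(pairs) + 1]] <- data.frame(id1 = h1, id2 = h2,
                                               r_true = 0.25, class = "half_sib")
      # first cousins via a full-sib pair
      a <- take("G1"); b <- take("G2")
      s1 <- sprintf("SB%03da", k); s2 <- sprintf("SB%03db", k)
      s1si <- draw_si_child(a$si, b$si); s2si <- draw_si_child(a$si, b$si)
      rows <- rbind(rows, child_row(s1, a$id, b$id, s1si),
                    child_row(s2, a$id, b$id, s2si))
      m1 <- take(setdiff(c("G1", "G2"), group_of(s1si)))
      m2 <- take(setdiff(c("G1", "G2"), group_of(s2si)))
      c1 <- sprintf("CZ%03da", k); c2 <- sprintf("CZ%03db", k)
      rows <- rbind(rows,
                    child_row(c1, s1, m1$id, draw_si_child(s1si, m1$si)),
                    child_row(c2, s2, m2$id, draw_si_child(s2si, m2$si)))
      pairs[[length(pairs) + 1]] <- data.frame(id1 = c1, id2 = c2,
                                               r_true = 0.125, class = "first_cousin")
      # unrelated founders
      u1 <- take("G1"); u2 <- take("G2")
      pairs[[length(pairs) + 1]] <- data.frame(id1 = u1$id, id2 = u2$id,
                                               r_true = 0, class = "unrelated")
    }
    NULL
  })
  list(ped = pedigree(rows), pairs = do.call(rbind, pairs))
}
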