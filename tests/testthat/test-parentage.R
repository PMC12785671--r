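test_that("locus trio verdicts equal exhaustive transmission enumeration", {
  gts <- all_genotypes(1:4)
  for (o in gts) for (m in gts) for (f in gts) {
    got <- locus_trio_compatible(o, m, f)
    expect_equal(got$verdict, oracle_trio_verdict(o, m, f),
                 info = paste(c(o, m, f), collapse = "/"))
    if (got$verdict == "mismatch")
      expect_equal(got$orphans, unique(o[!(o %in% c(m, f))]))
  }
  # missing anywhere skips the locus
  expect_equal(locus_trio_compatible(c(NA, NA), c(1, 2), c(1, 2))$verdict,
               "skipped")
  expect_equal(locus_trio_compatible(c(1, 2), c(1, 2), c(NA, NA))$verdict,
               "skipped")
})

test_that("the published trio worked examples reproduce exactly", {
  tab <- fixture_table()
  # the single-mismatch offspring: an orphan allele at DCA18
  tt <- trio_test(tab, "Don Carlo", "Frantoio", "Ascolana Tenera")
  expect_equal(tt$mismatch_count, 1)
  expect_equal(tt$mismatch_loci, "DCA18")
  expect_equal(tt$orphan_alleles$DCA18, 165L)
  # the fully compatible offspring
  expect_equal(trio_test(tab, "FS-17", "Frantoio", "Ascolana Tenera")$mismatch_count, 0)
  # single locus worked examples
  expect_equal(locus_trio_compatible(c(165, 177), c(177, 179), c(173, 177))$orphans, 165)
  expect_equal(locus_trio_compatible(c(231, 243), c(237, 243), c(231, 249))$verdict,
               "compatible")
  expect_error(trio_test(tab, "Nobody", "Frantoio", "FS-17"), "unknown")
})

test_that("selfing test rejects the self-pollination origin hypothesis", {
  tab <- fixture_table()
  st <- selfing_test(tab, "Don Carlo", "Frantoio")
  expect_equal(sort(st$mismatch_loci),
               sort(c("DCA3", "DCA9", "DCA16", "DCA18", "GAPU101",
                      "GAPU103a", "UDO43", "OeACP2")))
  expect_equal(st$mismatch_count, 8)
  # an offspring identical to a fully homozygous mother passes selfing
  hom <- make_table(list(rbind(c(5, 5), c(5, 5)), rbind(c(7, 7), c(7, 7))),
                    samples = c("kid", "mum"))
  expect_equal(selfing_test(hom, "kid", "mum")$mismatch_count, 0)
})

test_that("duo sharing is implied by trio compatibility", {
  tab <- fixture_table()
  expect_equal(duo_compatible(tab, "FS-17", "Frantoio")$mismatch_count, 0)
  expect_equal(duo_compatible(tab, "Don Carlo", "Ascolana Tenera")$mismatch_count, 0)
  dj <- make_table(list(rbind(c(1, 2), c(3, 4))), samples = c("kid", "par"))
  expect_equal(duo_compatible(dj, "kid", "par")$mismatch_count, 1)
  # logical implication on random tables
  set.seed(41)
  for (rep in 1:20) {
    calls <- lapply(1:5, function(l)
      matrix(sample(1:4, 6, replace = TRUE), 3, 2))
    tt <- make_table(calls, samples = c("o", "m", "f"))
    tr <- trio_test(tt, "o", "m", "f")
    dm <- duo_compatible(tt, "o", "m")
    ok <- tr$verdicts$verdict == "compatible"
    expect_true(all(dm$verdicts$verdict[ok] == "compatible"))
  }
})

test_that("mismatch counts are invariant to within-call allele order", {
  # the table constructor canonicalises, so feed swapped input files
  t1 <- make_table(list(rbind(c(2, 1), c(1, 3), c(2, 4))),
                   samples = c("o", "m", "f"))
  t2 <- make_table(list(rbind(c(1, 2), c(3, 1), c(4, 2))),
                   samples = c("o", "m", "f"))
  expect_equal(trio_test(t1, "o", "m", "f")$mismatch_count,
               trio_test(t2, "o", "m", "f")$mismatch_count)
})

test_that("candidate scan ranks the compatible father first and honours tolerance", {
  tab <- attach_si_groups(fixture_table(), fixture_si())
  rk <- scan_candidates(tab, "FS-17", known_mother = "Frantoio")
  expect_equal(rk$candidate[1], "Ascolana Tenera")
  expect_equal(rk$mismatch_count[1], 0)
  # zero tolerance drops the mutated trio, tolerance 1 recovers it
  rk0 <- scan_candidates(tab, "Don Carlo", known_mother = "Frantoio",
                         max_mismatch = 0)
  expect_false("Ascolana Tenera" %in% rk0$candidate)
  rk1 <- scan_candidates(tab, "Don Carlo", known_mother = "Frantoio",
                         max_mismatch = 1)
  expect_equal(rk1$candidate[1], "Ascolana Tenera")
})

test_that("SI-excluded candidates are retained, flagged and sorted last", {
  # offspring o; mother (G1); two fathers both trio-compatible, one G1
  calls <- list(rbind(c(1, 2), c(1, 1), c(2, 3), c(2, 4)),
                rbind(c(5, 6), c(5, 5), c(6, 7), c(6, 8)))
  tab <- make_table(calls, samples = c("o", "mum", "dadA", "dadB"))
  si <- data.frame(sample = c("o", "mum", "dadA", "dadB"),
                   si_group = c("G2", "G1", "G1", "G2"))
  rk <- scan_candidates(tab, "o", known_mother = "mum", si = si)
  expect_equal(rk$candidate, c("dadB", "dadA"))
  expect_equal(rk$si_excluded, c(FALSE, TRUE))
})

test_that("pair scanning without a known mother covers all unordered pairs", {
  tab <- fixture_table()
  rk <- scan_candidates(tab, "FS-17", max_mismatch = 12)
  expect_equal(nrow(rk), choose(3, 2))
  top <- rk[rk$mismatch_count == 0, ]
  expect_true(any(top$mother == "Ascolana Tenera" | top$father == "Ascolana Tenera"))
})

test_that("a simulated true father is recovered at rank 1 in most replicates", {
  hits <- vapply(1:40, function(k) {
    cfg <- sim_config(n_loci = 12, alleles_per_locus = c(6, 10),
                      mutation_rate = 0, seed = 1000 + k)
    sim <- simulate_dataset(cfg, "trios_panel", n_trios = 1, n_extra = 60)
    rk <- scan_candidates(sim$table, "O001", known_mother = "F001",
                          max_mismatch = 1)
    nrow(rk) > 0 && rk$candidate[1] == "F002"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("mutation produces mismatches at roughly twice the per-meiosis rate", {
  # mu = 0.05 at 100 loci: about 2*mu*L transmissions mutate; most create a
  # detectable orphan, a minority coincide with a parental allele
  cfg <- sim_config(n_loci = 100, alleles_per_locus = c(6, 10),
                    mutation_rate = 0.05, seed = 53)
  counts <- vapply(1:30, function(k) {
    cfgk <- sim_config(n_loci = 100, alleles_per_locus = c(6, 10),
                       mutation_rate = 0.05, seed = 53 + k)
    sim <- simulate_dataset(cfgk, "trios_panel", n_trios = 1, n_extra = 0)
    tt <- trio_test(sim$table, "O001", "F001", "F002")
    # cross-check against the enumeration oracle
    go <- sample_genotypes(sim$table, "O001")
    gm <- sample_genotypes(sim$table, "F001")
    gf <- sample_genotypes(sim$table, "F002")
    oracle <- sum(vapply(1:100, function(l)
      oracle_trio_verdict(go[l, ], gm[l, ], gf[l, ]) == "mismatch", logical(1)))
    expect_equal(tt$mismatch_count, oracle)
    tt$mismatch_count
  }, numeric(1))
  expected_full <- 2 * 0.05 * 100
  expect_gt(mean(counts), 0.5 * expected_full)
  expect_lt(mean(counts), 1.1 * expected_full)
})
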