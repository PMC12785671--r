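#' Simulate a complete benchmark dataset
#'
#' Builds a named pedigree scenario, simulates founder genotypes, drops
#' alleles through the pedigree and returns the genotype table together
#' with its exact expected-relatedness truth table. Built-in scenarios:
#'
#' * `trios_panel`: `n_trios` parent pairs (mother G1, father G2), one
#'   offspring each, plus `n_extra` unrelated founders as distractors.
#' * `mixed_kinship_panel`: a 24-individual panel containing a clone pair,
#'   parent-offspring trios, full sibs, a half sib, first cousins, second
#'   cousins and unrelated founders.
#' * `olive_like_102`: a 102-individual panel at 12 loci emulating a
#'   cultivar collection: 88 founders, three clones (synonyms), two
#'   two-offspring families, a half sib, a full-sib pair and first- and
#'   second-cousin pairs.
#'
#' All randomness derives from `cfg$seed` through named streams, so the
#' same configuration reproduces byte-identical outputs.
#'
#' @param cfg A [sim_config].
#' @param scenario Scenario name, or a user [pedigree] whose founders will
#'   be simulated.
#' @param n_trios,n_extra `trios_panel` sizes.
#' @param pseudo_self Passed to [drop_alleles()].
#' @return List with `table` ([genotype_table]), `truth` (truth table from
#'   [expected_relatedness()]), `pedigree`, `freqs` (true founder
#'   frequencies) and `si` (data frame `sample,si_group`).
#' @export
simulate_dataset <- function(cfg, scenario = "olive_like_102", n_trios = 10,
                             n_extra = 10, pseudo_self = FALSE) {
  builtins <- c("trios_panel", "mixed_kinship_panel", "olive_like_102")
  if (inherits(scenario, "data.frame")) {
    ped <- pedigree(scenario)
  } else {
    if (!scenario %in% builtins)
      stop("unknown scenario '", scenario, "'; built-ins: ",
           paste(builtins, collapse = ", "))
    ped <- switch(scenario,
                  trios_panel = build_trios_panel(cfg, n_trios, n_extra),
                  mixed_kinship_panel = build_mixed_panel(cfg),
                  olive_like_102 = build_olive_like(cfg))
  }
  fnd_ids <- ped$id[is_founder(ped)]
  si_known <- !is.na(ped$si_genotype[is_founder(ped)])
  fou <- simulate_founders(cfg, length(fnd_ids), ids = fnd_ids,
                           si_groups = if (all(si_known))
                             group_of(ped$si_genotype[is_founder(ped)]) else NULL)
  tab <- drop_alleles(ped, fou$table, cfg, pseudo_self = pseudo_self)
  truth <- expected_relatedness(ped)
  list(table = tab, truth = truth, pedigree = ped, freqs = fou$freqs,
       si = tab$samples[c("sample", "si_group")])
}

# Founder SI groups alternate G1/G2 so that consecutive founder pairs are
# always cross-compatible; scenario builders rely on that layout.
alt_si <- function(k) ifelse(seq_len(k) %% 2 == 1, "S1S2", "S1S1")

founder_rows <- function(ids, si) {
  data.frame(id = ids, mother = NA_character_, father = NA_character_,
             clone_of = NA_character_, si_genotype = si,
             stringsAsFactors = FALSE)
}

child_row <- function(id, mother, father, si = NA_character_) {
  data.frame(id = id, mother = mother, father = father,
             clone_of = NA_character_, si_genotype = si,
             stringsAsFactors = FALSE)
}

clone_row <- function(id, src, si = NA_character_) {
  data.frame(id = id, mother = NA_character_, father = NA_character_,
             clone_of = src, si_genotype = si, stringsAsFactors = FALSE)
}

# Offspring SI genotypes are resolved at build time (stream "si") so that
# later generations can be mated to SI-compatible partners.
draw_si_child <- function(m_si, f_si) si_cross_offspring(m_si, f_si)

build_trios_panel <- function(cfg, n_trios, n_extra) {
  nf <- 2 * n_trios + n_extra
  si <- alt_si(nf)
  fids <- sprintf("F%03d", seq_len(nf))
  rows <- founder_rows(fids, si)
  with_stream(cfg$seed, "si", {
    for (k in seq_len(n_trios)) {
      m <- fids[2 * k - 1]; f <- fids[2 * k]
      rows <- rbind(rows, child_row(sprintf("O%03d", k), m, f,
                                    draw_si_child(si[2 * k - 1], si[2 * k])))
    }
    NULL
  })
  pedigree(rows)
}

# Pick the first founder in `pool` with SI group opposite to `si`, marking
# it used (environment side effect keeps the builder readable).
take_mate <- function(env, si_geno) {
  need <- setdiff(c("G1", "G2"), group_of(si_geno))
  i <- which(group_of(env$si[env$pool]) == need & !env$used[env$pool])[1]
  if (is.na(i)) stop("no SI-compatible mate available in founder pool")
  idx <- env$pool[i]
  env$used[idx] <- TRUE
  list(id = env$fids[idx], si = env$si[idx])
}

build_mixed_panel <- function(cfg) {
  nf <- 14
  si <- alt_si(nf)
  fids <- sprintf("F%02d", seq_len(nf))
  e <- new.env()
  e$si <- si; e$fids <- fids; e$pool <- 7:14; e$used <- rep(FALSE, nf)
  rows <- founder_rows(fids, si)
  with_stream(cfg$seed, "si", {
    rows <- rbind(rows, clone_row("F01_clone", "F01", si[1]))
    s01 <- draw_si_child(si[1], si[2]); s02 <- draw_si_child(si[1], si[2])
    s03 <- draw_si_child(si[1], si[4])
    rows <- rbind(rows,
                  child_row("S01", "F01", "F02", s01),
                  child_row("S02", "F01", "F02", s02),
                  child_row("S03", "F01", "F04", s03))
    s04 <- draw_si_child(si[5], si[6]); s05 <- draw_si_child(si[5], si[6])
    rows <- rbind(rows,
                  child_row("S04", "F05", "F06", s04),
                  child_row("S05", "F05", "F06", s05))
    m1 <- take_mate(e, s04); m2 <- take_mate(e, s05)
    c01 <- draw_si_child(s04, m1$si); c02 <- draw_si_child(s05, m2$si)
    rows <- rbind(rows,
                  child_row("C01", "S04", m1$id, c01),
                  child_row("C02", "S05", m2$id, c02))
    m3 <- take_mate(e, c01); m4 <- take_mate(e, c02)
    rows <- rbind(rows,
                  child_row("CC01", "C01", m3$id, draw_si_child(c01, m3$si)),
                  child_row("CC02", "C02", m4$id, draw_si_child(c02, m4$si)))
    NULL
  })
  pedigree(rows)
}

build_olive_like <- function(cfg) {
  nf <- 88
  si <- alt_si(nf)
  fids <- sprintf("F%03d", seq_len(nf))
  e <- new.env()
  e$si <- si; e$fids <- fids; e$pool <- 13:88; e$used <- rep(FALSE, nf)
  rows <- founder_rows(fids, si)
  with_stream(cfg$seed, "si", {
    rows <- rbind(rows,
                  clone_row("F001_syn", "F001", si[1]),
                  clone_row("F002_syn", "F002", si[2]),
                  clone_row("F003_syn", "F003", si[3]))
    # family 1: two full-sib offspring of F005 x F006 plus a maternal half sib
    o1 <- draw_si_child(si[5], si[6]); o2 <- draw_si_child(si[5], si[6])
    o3 <- draw_si_child(si[5], si[8])
    rows <- rbind(rows,
                  child_row("O001", "F005", "F006", o1),
                  child_row("O002", "F005", "F006", o2),
                  child_row("O003", "F005", "F008", o3))
    # family 2
    o4 <- draw_si_child(si[9], si[10]); o5 <- draw_si_child(si[9], si[10])
    rows <- rbind(rows,
                  child_row("O004", "F009", "F010", o4),
                  child_row("O005", "F009", "F010", o5))
    # cousin lineage
    s1 <- draw_si_child(si[11], si[12]); s2 <- draw_si_child(si[11], si[12])
    rows <- rbind(rows,
                  child_row("S001", "F011", "F012", s1),
                  child_row("S002", "F011", "F012", s2))
    m1 <- take_mate(e, s1); m2 <- take_mate(e, s2)
    c1 <- draw_si_child(s1, m1$si); c2 <- draw_si_child(s2, m2$si)
    rows <- rbind(rows,
                  child_row("C001", "S001", m1$id, c1),
                  child_row("C002", "S002", m2$id, c2))
    m3 <- take_mate(e, c1); m4 <- take_mate(e, c2)
    rows <- rbind(rows,
                  child_row("CC001", "C001", m3$id, draw_si_child(c1, m3$si)),
                  child_row("CC002", "C002", m4$id, draw_si_child(c2, m4$si)))
    NULL
  })
  pedigree(rows)
}
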