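#' Simulation configuration
#'
#' Collects the knobs of the synthetic-genotype generator. Defaults emulate
#' a cultivar panel typed at 12 multi-allelic SSR/indel loci with allele
#' sizes on a dinucleotide grid between 120 and 470 bp and 2-10 alleles per
#' locus.
#'
#' @param n_loci Number of loci.
#' @param alleles_per_locus Integer count or length-2 range; the per-locus
#'   allele number is drawn uniformly from the range.
#' @param dirichlet_alpha Dirichlet concentration for founder allele
#'   frequencies (1 = uniform over the simplex).
#' @param motif_step Repeat-motif length in bp (mutation step size).
#' @param base_allele_range Allele size interval in bp.
#' @param mutation_rate Per-allele, per-meiosis stepwise mutation
#'   probability (default 1e-3, a conventional microsatellite order of
#'   magnitude).
#' @param error_rate Per-allele genotyping-error probability (an erroneous
#'   allele is replaced by a random allele from the locus allele set).
#' @param prop_g1 Proportion of founders assigned SI group G1 (S1S2).
#' @param seed Integer seed; all stages draw from named streams derived
#'   from it, so e.g. changing `error_rate` does not perturb founder draws.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_loci = 12, alleles_per_locus = c(2, 10),
                       dirichlet_alpha = 1, motif_step = 2,
                       base_allele_range = c(120, 470),
                       mutation_rate = 1e-3, error_rate = 0,
                       prop_g1 = 0.5, seed = 1) {
  if (n_loci < 1) stop("n_loci must be >= 1")
  rates <- c(mutation_rate, error_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (length(alleles_per_locus) == 1)
    alleles_per_locus <- rep(alleles_per_locus, 2)
  structure(list(n_loci = n_loci, alleles_per_locus = alleles_per_locus,
                 dirichlet_alpha = dirichlet_alpha, motif_step = motif_step,
                 base_allele_range = base_allele_range,
                 mutation_rate = mutation_rate, error_rate = error_rate,
                 prop_g1 = prop_g1, seed = seed),
            class = "sim_config")
}

#' Simulate founder genotypes under Hardy-Weinberg equilibrium
#'
#' Per locus: an allele count is drawn from the configured range, allele
#' sizes are placed on the motif grid inside `base_allele_range`, allele
#' frequencies are drawn from a symmetric Dirichlet, and founder genotypes
#' are formed by two independent allele draws (HWE). Founders receive SI
#' genotypes S1S2/S1S1 with proportion `prop_g1`.
#'
#' @param cfg A [sim_config].
#' @param n Number of founders.
#' @param ids Optional character ids (default `F001`, `F002`, ...).
#' @param si_groups Optional character vector of SI groups (`"G1"`/`"G2"`)
#'   overriding the random assignment.
#' @return List with `table` (a [genotype_table]), `freqs` (the true
#'   `allele_freq_table`) and `si_genotypes` (character vector).
#' @export
simulate_founders <- function(cfg, n, ids = NULL, si_groups = NULL) {
  if (n < 1) stop("n must be >= 1")
  ids <- ids %||% sprintf("F%03d", seq_len(n))
  lo <- cfg$base_allele_range[1]; hi <- cfg$base_allele_range[2]
  grid_max <- (hi - lo) %/% cfg$motif_step + 1
  with_stream(cfg$seed, "founders", {
    loci_alleles <- vector("list", cfg$n_loci)
    freqs <- vector("list", cfg$n_loci)
    a <- matrix(NA_integer_, n, cfg$n_loci)
    b <- matrix(NA_integer_, n, cfg$n_loci)
    kk <- cfg$alleles_per_locus[1]:cfg$alleles_per_locus[2]
    for (l in seq_len(cfg$n_loci)) {
      k <- kk[sample.int(length(kk), 1)]
      if (k > grid_max)
        stop("alleles_per_locus exceeds motif grid inside base_allele_range")
      base <- lo + cfg$motif_step *
        sample.int(grid_max - k + 1, 1) - cfg$motif_step
      alleles <- base + cfg$motif_step * (seq_len(k) - 1)
      w <- stats::rgamma(k, shape = cfg$dirichlet_alpha)
      p <- w / sum(w)
      names(p) <- alleles
      attr(p, "n_obs") <- Inf
      freqs[[l]] <- p
      loci_alleles[[l]] <- alleles
      draws <- alleles[sample.int(k, 2 * n, replace = TRUE, prob = p)]
      a[, l] <- draws[seq_len(n)]
      b[, l] <- draws[n + seq_len(n)]
    }
    names(freqs) <- sprintf("L%02d", seq_len(cfg$n_loci))
    si_groups <- si_groups %||%
      sample(c("G1", "G2"), n, replace = TRUE,
             prob = c(cfg$prop_g1, 1 - cfg$prop_g1))
    tab <- genotype_table(a, b,
                          data.frame(sample = ids, population = "SIM",
                                     si_group = si_groups),
                          data.frame(locus = names(freqs)))
    list(table = tab, freqs = structure(freqs, class = "allele_freq_table"),
         si_genotypes = si_genotype_of_group(si_groups))
  })
}

#' Construct a validated pedigree
#'
#' A pedigree is a data frame with columns `id`, `mother`, `father`
#' (both `NA` for founders), optional `clone_of` (vegetatively propagated
#' duplicate of an earlier individual) and optional `si_genotype`
#' (`"S1S1"`/`"S1S2"`). Parents and clone sources must precede their
#' dependants, which also guarantees acyclicity.
#'
#' @param df Data frame as described.
#' @return The validated data frame with class `pedigree`.
#' @export
pedigree <- function(df) {
  df <- as.data.frame(df)
  if (!"clone_of" %in% names(df)) df$clone_of <- NA_character_
  if (!"si_genotype" %in% names(df)) df$si_genotype <- NA_character_
  if (anyDuplicated(df$id)) stop("duplicate pedigree id")
  seen <- character()
  for (i in seq_len(nrow(df))) {
    refs <- stats::na.omit(c(df$mother[i], df$father[i], df$clone_of[i]))
    if (df$id[i] %in% refs)
      stop("pedigree cycle: '", df$id[i], "' references itself")
    bad <- setdiff(refs, seen)
    if (length(bad))
      stop("pedigree not in ancestral order (or cyclic): '", df$id[i],
           "' references '", bad[1], "' which does not precede it")
    if (xor(is.na(df$mother[i]), is.na(df$father[i])))
      stop("individual '", df$id[i], "' has exactly one parent")
    if (!is.na(df$clone_of[i]) && !is.na(df$mother[i]))
      stop("individual '", df$id[i], "' cannot be both clone and offspring")
    seen <- c(seen, df$id[i])
  }
  class(df) <- c("pedigree", "data.frame")
  df
}

is_founder <- function(ped) is.na(ped$mother) & is.na(ped$clone_of)

#' Transmit founder genotypes through a pedigree
#'
#' Gene dropping with a stepwise mutation model: each non-founder receives
#' one uniformly chosen allele per parent per locus; each transmitted
#' allele mutates with probability `mutation_rate` by plus or minus one
#' motif step (equal probability, reflecting at the allele-range bounds);
#' genotyping error then replaces each allele independently with a random
#' in-locus allele at `error_rate`. Clones copy their source genotype
#' (subject to genotyping error only). SI genotypes are transmitted
#' Mendelianly where the pedigree does not fix them; matings within an SI
#' group raise an error unless `pseudo_self = TRUE`.
#'
#' @param ped A [pedigree]; its founders must all be in `founders`.
#' @param founders Founder [genotype_table] (from [simulate_founders()]).
#' @param cfg The [sim_config].
#' @param pseudo_self Allow within-SI-group matings.
#' @param si_genotypes Optional named character vector of founder S-locus
#'   genotypes; defaults to the founder table's `si_group` labels.
#' @return A [genotype_table] over all pedigree individuals, with
#'   `si_group` filled from the realised S-locus genotypes.
#' @export
drop_alleles <- function(ped, founders, cfg, pseudo_self = FALSE,
                         si_genotypes = NULL) {
  ped <- pedigree(ped)
  n <- nrow(ped); L <- n_loci(founders)
  fnd <- is_founder(ped)
  miss <- setdiff(ped$id[fnd], founders$samples$sample)
  if (length(miss)) stop("founder '", miss[1], "' absent from founder table")
  locus_alleles <- lapply(seq_len(L), function(l)
    sort(unique(stats::na.omit(c(founders$a[, l], founders$b[, l])))))
  a <- matrix(NA_integer_, n, L); b <- matrix(NA_integer_, n, L)
  rownames(a) <- rownames(b) <- ped$id
  si <- ped$si_genotype
  fidx <- match(ped$id, founders$samples$sample)
  for (i in which(fnd)) {
    a[i, ] <- founders$a[fidx[i], ]; b[i, ] <- founders$b[fidx[i], ]
    if (is.na(si[i])) {
      si[i] <- if (!is.null(si_genotypes)) si_genotypes[[ped$id[i]]] else
        si_genotype_of_group(founders$samples$si_group[fidx[i]])
    }
  }
  # transmission pass (gamete choice), then mutation, then error: named
  # streams keep the three independent.
  with_stream(cfg$seed, "transmission", {
    for (i in seq_len(n)) {
      if (fnd[i]) next
      if (!is.na(ped$clone_of[i])) {
        src <- match(ped$clone_of[i], ped$id)
        a[i, ] <- a[src, ]; b[i, ] <- b[src, ]
        if (is.na(si[i])) si[i] <- si[src]
        next
      }
      mi <- match(ped$mother[i], ped$id); fi <- match(ped$father[i], ped$id)
      if (is.na(si[i])) si[i] <- si_cross_offspring(si[mi], si[fi])
      if (!pseudo_self && group_of(si[mi]) == group_of(si[fi]))
        stop("SI-incompatible mating for '", ped$id[i], "': both parents in ",
             group_of(si[mi]))
      pickm <- stats::runif(L) < 0.5
      pickf <- stats::runif(L) < 0.5
      a[i, ] <- ifelse(pickm, a[mi, ], b[mi, ])
      b[i, ] <- ifelse(pickf, a[fi, ], b[fi, ])
    }
    NULL
  })
  if (cfg$mutation_rate > 0) {
    with_stream(cfg$seed, "mutation", {
      nonf <- which(!fnd & is.na(ped$clone_of))
      for (i in nonf) {
        for (m in list(quote(a), quote(b))) {
          mat <- eval(m)
          hit <- stats::runif(L) < cfg$mutation_rate
          if (any(hit)) {
            step <- ifelse(stats::runif(sum(hit)) < 0.5, -1, 1) * cfg$motif_step
            newv <- mat[i, hit] + step
            # reflect at the representable range bounds
            out <- newv < cfg$base_allele_range[1] | newv > cfg$base_allele_range[2]
            newv[out] <- mat[i, hit][out] - step[out]
            mat[i, hit] <- newv
            if (identical(m, quote(a))) a <- mat else b <- mat
          }
        }
      }
      NULL
    })
  }
  if (cfg$error_rate > 0) {
    with_stream(cfg$seed, "error", {
      for (i in seq_len(n)) {
        for (nm in c("a", "b")) {
          mat <- if (nm == "a") a else b
          hit <- which(stats::runif(L) < cfg$error_rate & !is.na(mat[i, ]))
          for (l in hit) {
            al <- locus_alleles[[l]]
            mat[i, l] <- al[sample.int(length(al), 1)]
          }
          if (nm == "a") a <- mat else b <- mat
        }
      }
      NULL
    })
  }
  genotype_table(a, b,
                 data.frame(sample = ped$id, population = "SIM",
                            si_group = group_of(si)),
                 founders$loci)
}

#' Exact pedigree-expected relatedness (truth table)
#'
#' Kinship coefficients by the standard recursion: founders are non-inbred
#' and mutually unrelated (`phi(i,i) = 1/2`, pairwise 0);
#' `phi(i,i) = (1 + phi(mother_i, father_i)) / 2`; for `i` later in the
#' pedigree than `j`, `phi(i,j) = (phi(mother_i, j) + phi(father_i, j)) / 2`.
#' Clones inherit their source's kinship values, so a clone pair has
#' `r = 1`. The reported dyad relatedness is `r = 2 phi`, capped at 1. For
#' dyads involving inbred individuals (possible only under pseudo-self
#' matings) `2 phi` exceeds the three-state IBD relatedness that the
#' likelihood estimators target — e.g. a selfed offspring with its parent
#' has `2 phi = 1` while gamete enumeration of shared-IBD classes gives
#' 0.75 — and is reported unrenormalised; see the package vignette.
#'
#' @param ped A [pedigree].
#' @return A `truth_table` data frame: `id1`, `id2` (lexicographic),
#'   `r_true`, `relationship` label.
#' @export
expected_relatedness <- function(ped) {
  ped <- pedigree(ped)
  n <- nrow(ped)
  src <- match(ifelse(is.na(ped$clone_of), ped$id, ped$clone_of), ped$id)
  # resolve clone chains
  repeat {
    s2 <- src[src]
    if (identical(s2, src)) break
    src <- s2
  }
  phi <- matrix(0, n, n)
  mi <- match(ped$mother, ped$id); fi <- match(ped$father, ped$id)
  for (i in seq_len(n)) {
    if (src[i] != i) {                       # clone: copy source rows
      phi[i, seq_len(i)] <- phi[src[i], seq_len(i)]
      phi[seq_len(i), i] <- phi[i, seq_len(i)]
      phi[i, i] <- phi[src[i], src[i]]
      next
    }
    if (is.na(mi[i])) {
      phi[i, i] <- 0.5
    } else {
      phi[i, i] <- 0.5 * (1 + phi[mi[i], fi[i]])
      if (i > 1) {
        js <- seq_len(i - 1)
        phi[i, js] <- 0.5 * (phi[mi[i], js] + phi[fi[i], js])
        phi[js, i] <- phi[i, js]
      }
    }
  }
  prs <- utils::combn(n, 2)
  id1 <- ped$id[prs[1, ]]; id2 <- ped$id[prs[2, ]]
  swap <- id1 > id2
  tmp <- id1[swap]; id1[swap] <- id2[swap]; id2[swap] <- tmp
  r <- pmin(2 * phi[cbind(prs[1, ], prs[2, ])], 1)
  rel <- vapply(seq_len(ncol(prs)), function(k)
    relationship_label(ped, src, prs[1, k], prs[2, k],
                       r[k]), character(1))
  structure(data.frame(id1 = id1, id2 = id2, r_true = r, relationship = rel,
                       stringsAsFactors = FALSE),
            class = c("truth_table", "data.frame"))
}

relationship_label <- function(ped, src, i, j, r) {
  if (src[i] == src[j]) return("clone")
  canon <- function(p) {                    # map parent ids through clones
    idx <- match(p, ped$id)
    ifelse(is.na(idx), p, ped$id[src[idx]])
  }
  pi_ <- canon(c(ped$mother[src[i]], ped$father[src[i]]))
  pj <- canon(c(ped$mother[src[j]], ped$father[src[j]]))
  if (ped$id[src[j]] %in% pi_ || ped$id[src[i]] %in% pj)
    return("parent_offspring")
  if (!anyNA(pi_) && !anyNA(pj) && setequal(pi_, pj)) return("full_sib")
  shared <- length(intersect(stats::na.omit(pi_), stats::na.omit(pj)))
  if (shared == 1) return("half_sib")
  if (r == 0) return("unrelated")
  if (isTRUE(all.equal(r, 0.125))) return("first_cousin")
  if (isTRUE(all.equal(r, 0.03125))) return("second_cousin")
  "other"
}
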