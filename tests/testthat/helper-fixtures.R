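# Shared fixtures and independent oracles used across test files.

fixture_path <- function(f) system.file("extdata", f, package = "olivekin")

fixture_table <- function() read_genotype_csv(fixture_path("table1_genotypes.csv"))

fixture_si <- function() read_si_csv(fixture_path("table2_si_groups.csv"))

# Small genotype table from a compact spec: loci are columns of a list,
# each entry a 2-column matrix of alleles (NA = missing).
make_table <- function(calls, samples = NULL, loci = NULL) {
  n <- nrow(calls[[1]])
  samples <- samples %||% paste0("S", seq_len(n))
  loci <- loci %||% paste0("L", seq_along(calls))
  a <- sapply(calls, function(m) m[, 1])
  b <- sapply(calls, function(m) m[, 2])
  if (n == 1) { a <- matrix(a, 1); b <- matrix(b, 1) }
  genotype_table(a, b, samples, loci)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -------------------------------------------------

# Brute-force trio verdict: enumerate the four ordered transmissions
# (mother passes allele 1 or 2, father passes allele 1 or 2).
oracle_trio_verdict <- function(o, m, f) {
  if (anyNA(c(o, m, f))) return("skipped")
  for (i in 1:2) for (j in 1:2)
    if (setequal_multiset(sort(c(m[i], f[j])), sort(o))) return("compatible")
  "mismatch"
}

setequal_multiset <- function(x, y) all(sort(x) == sort(y))

# Per-locus codominant squared distance via explicit allele-count vectors.
oracle_locus_distance <- function(g1, g2) {
  alleles <- sort(unique(c(g1, g2)))
  x <- sapply(alleles, function(a) sum(g1 == a))
  y <- sapply(alleles, function(a) sum(g2 == a))
  0.5 * sum((x - y)^2)
}

oracle_pair_distance <- function(tab, i, j) {
  tot <- 0
  for (l in seq_len(n_loci(tab))) {
    g1 <- c(tab$a[i, l], tab$b[i, l]); g2 <- c(tab$a[j, l], tab$b[j, l])
    if (anyNA(c(g1, g2))) next
    tot <- tot + oracle_locus_distance(g1, g2)
  }
  tot
}

# Naive Ward agglomeration: recompute the within-cluster sum of squared
# distances (ESS) increase for every cluster pair at every step, O(n^3).
# Returns the merge sequence as canonical member-set strings.
oracle_ward_merges <- function(d) {
  n <- nrow(d)
  ess <- function(members) {
    if (length(members) < 2) return(0)
    sum(d[members, members]^2) / (2 * length(members))
  }
  clusters <- as.list(seq_len(n))
  merges <- character(0)
  while (length(clusters) > 1) {
    best <- NULL; best_delta <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        delta <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (delta < best_delta - 1e-12) { best_delta <- delta; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges <- c(merges, paste(merged, collapse = ","))
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  merges
}

# Merge sequence of an hclust result in the same canonical form.
hclust_merges <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  out <- character(nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[k]] <- sort(c(grab(hc$merge[k, 1]), grab(hc$merge[k, 2])))
    out[k] <- paste(sets[[k]], collapse = ",")
  }
  out
}

# Gene-dropping Monte-Carlo estimate of dyad IBD sharing (k1/2 + k2).
oracle_gene_drop <- function(ped, dyads, reps = 20000, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  lab <- vector("list", n)
  names(lab) <- ped$id
  next_label <- 1L
  for (i in seq_len(n)) {
    if (!is.na(ped$clone_of[i])) {
      lab[[i]] <- lab[[match(ped$clone_of[i], ped$id)]]
    } else if (is.na(ped$mother[i])) {
      lab[[i]] <- cbind(rep(next_label, reps), rep(next_label + 1L, reps))
      next_label <- next_label + 2L
    } else {
      m <- lab[[match(ped$mother[i], ped$id)]]
      f <- lab[[match(ped$father[i], ped$id)]]
      pm <- sample.int(2, reps, replace = TRUE)
      pf <- sample.int(2, reps, replace = TRUE)
      lab[[i]] <- cbind(m[cbind(seq_len(reps), pm)],
                        f[cbind(seq_len(reps), pf)])
    }
  }
  vapply(seq_len(nrow(dyads)), function(k) {
    x <- lab[[match(dyads$id1[k], ped$id)]]
    y <- lab[[match(dyads$id2[k], ped$id)]]
    s1 <- (x[, 1] == y[, 1]) + (x[, 2] == y[, 2])
    s2 <- (x[, 1] == y[, 2]) + (x[, 2] == y[, 1])
    mean(pmax(s1, s2)) / 2
  }, numeric(1))
}

# All unordered genotypes over a small allele set.
all_genotypes <- function(alleles) {
  gs <- list()
  for (i in seq_along(alleles)) for (j in i:length(alleles))
    gs[[length(gs) + 1]] <- c(alleles[i], alleles[j])
  gs
}

hwe_prob <- function(g, p) {
  pi_ <- p[as.character(g[1])]; pj <- p[as.character(g[2])]
  if (g[1] == g[2]) unname(pi_^2) else unname(2 * pi_ * pj)
}
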