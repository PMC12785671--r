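#' Mendelian trio compatibility at a single locus
#'
#' A locus is trio-compatible when the offspring's two alleles admit an
#' ordered assignment — one allele inherited from the mother, the other
#' from the father — i.e. some ordering `(x, y)` of the offspring alleles
#' has `x` among the mother's alleles and `y` among the father's. Any
#' missing call makes the locus `"skipped"`. On a mismatch, offspring
#' alleles found in neither parent are reported as orphan alleles
#' (candidate mutations or genotyping errors).
#'
#' @param o,m,f Length-2 integer vectors: offspring, mother, father calls.
#' @return List with `verdict` (`"compatible"`, `"mismatch"`, `"skipped"`)
#'   and `orphans` (integer vector, possibly empty).
#' @export
locus_trio_compatible <- function(o, m, f) {
  if (anyNA(o) || anyNA(m) || anyNA(f))
    return(list(verdict = "skipped", orphans = integer()))
  ok <- (o[1] %in% m && o[2] %in% f) || (o[2] %in% m && o[1] %in% f)
  if (ok) return(list(verdict = "compatible", orphans = integer()))
  list(verdict = "mismatch", orphans = unique(o[!(o %in% c(m, f))]))
}

#' Trio, selfing and duo parentage tests
#'
#' `trio_test()` applies [locus_trio_compatible()] at every locus for a
#' putative (offspring, mother, father) trio. `selfing_test()` is the same
#' test with the father set equal to the mother (did the offspring arise by
#' self-pollination?). `duo_compatible()` tests single-parent sharing: a
#' locus is compatible when offspring and parent share at least one allele.
#' Missing loci are skipped and excluded from mismatch counts; a skipped
#' count is reported so low-overlap comparisons remain visible.
#'
#' @param table A [genotype_table].
#' @param offspring,mother,father Sample ids present in the table.
#' @return A `trio_result`: list with the ids, a per-locus data frame
#'   `verdicts` (`locus`, `verdict`, `orphans`), `mismatch_count`,
#'   `mismatch_loci`, `skipped_loci` and `orphan_alleles` (named list,
#'   mismatching locus -> orphan alleles).
#' @export
trio_test <- function(table, offspring, mother, father) {
  go <- sample_genotypes(table, offspring)
  gm <- sample_genotypes(table, mother)
  gf <- sample_genotypes(table, father)
  loci <- table$loci$locus
  res <- lapply(seq_along(loci), function(l)
    locus_trio_compatible(go[l, ], gm[l, ], gf[l, ]))
  verdicts <- vapply(res, `[[`, character(1), "verdict")
  orphans <- lapply(res, `[[`, "orphans")
  names(orphans) <- loci
  mm <- loci[verdicts == "mismatch"]
  structure(list(offspring = offspring, mother = mother, father = father,
                 verdicts = data.frame(locus = loci, verdict = verdicts,
                                       orphans = vapply(orphans, function(x)
                                         paste(x, collapse = ";"), character(1)),
                                       row.names = NULL),
                 mismatch_count = length(mm), mismatch_loci = mm,
                 skipped_loci = loci[verdicts == "skipped"],
                 orphan_alleles = orphans[verdicts == "mismatch"]),
            class = "trio_result")
}

#' @export
print.trio_result <- function(x, ...) {
  cat(sprintf("trio test: %s | mother %s x father %s\n", x$offspring,
              x$mother, x$father))
  cat(sprintf("  %d mismatching loci%s; %d skipped\n", x$mismatch_count,
              if (x$mismatch_count) paste0(" (", paste(x$mismatch_loci, collapse = ", "), ")") else "",
              length(x$skipped_loci)))
  invisible(x)
}

#' @rdname trio_test
#' @export
selfing_test <- function(table, offspring, mother) {
  res <- trio_test(table, offspring, mother, mother)
  res$father <- res$mother
  res
}

#' @rdname trio_test
#' @param parent Sample id of the single putative parent.
#' @export
duo_compatible <- function(table, offspring, parent) {
  go <- sample_genotypes(table, offspring)
  gp <- sample_genotypes(table, parent)
  loci <- table$loci$locus
  verdicts <- vapply(seq_along(loci), function(l) {
    o <- go[l, ]; p <- gp[l, ]
    if (anyNA(o) || anyNA(p)) "skipped"
    else if (any(o %in% p)) "compatible" else "mismatch"
  }, character(1))
  mm <- loci[verdicts == "mismatch"]
  structure(list(offspring = offspring, mother = parent, father = NA_character_,
                 verdicts = data.frame(locus = loci, verdict = verdicts,
                                       orphans = "", row.names = NULL),
                 mismatch_count = length(mm), mismatch_loci = mm,
                 skipped_loci = loci[verdicts == "skipped"],
                 orphan_alleles = list()),
            class = "trio_result")
}

#' Scan candidate parents for an offspring
#'
#' With a known mother, every other sample is tested as the father via
#' [trio_test()]; without one, all unordered pairs of candidates are tested
#' as (mother, father). Candidates exceeding `max_mismatch` mismatching
#' loci are dropped — the default tolerance of 1 accommodates a sporadic
#' microsatellite mutation or genotyping error in an otherwise compatible
#' trio. Candidates excluded by the self-incompatibility rule (same SI
#' group as the known mother) are retained but flagged and sorted last.
#' Ranking order: SI-excluded ascending, mismatches ascending, relatedness
#' to the offspring descending, id ascending.
#'
#' @param table A [genotype_table].
#' @param offspring Offspring sample id.
#' @param known_mother Optional sample id of the known mother.
#' @param max_mismatch Maximum tolerated mismatching loci (default 1).
#' @param si Optional data frame `sample,si_group` (see [read_si_csv()]);
#'   defaults to the table's own labels when present.
#' @param rmatrix Optional `relatedness_matrix` supplying the r tie-breaker.
#' @return A `candidate_ranking` data frame: `candidate` (or
#'   `mother`/`father` when scanning pairs), `mismatch_count`,
#'   `skipped_loci`, `r`, `si_excluded`.
#' @export
scan_candidates <- function(table, offspring, known_mother = NULL,
                            max_mismatch = 1, si = NULL, rmatrix = NULL) {
  if (max_mismatch < 0) stop("max_mismatch must be >= 0")
  ids <- table$samples$sample
  if (!offspring %in% ids) stop("unknown offspring id: ", offspring)
  si_of <- function(id) {
    if (!is.null(si)) {
      v <- si$si_group[match(id, si$sample)]
    } else v <- table$samples$si_group[match(id, ids)]
    if (length(v) == 0) NA_character_ else v
  }
  r_of <- function(id) {
    if (is.null(rmatrix)) return(NA_real_)
    rmatrix$r[offspring, id]
  }
  if (!is.null(known_mother)) {
    if (!known_mother %in% ids) stop("unknown mother id: ", known_mother)
    cand <- setdiff(ids, c(offspring, known_mother))
    rows <- lapply(cand, function(f) {
      tt <- trio_test(table, offspring, known_mother, f)
      excl <- !is.na(si_of(f)) && !is.na(si_of(known_mother)) &&
        si_of(f) == si_of(known_mother)
      data.frame(candidate = f, mismatch_count = tt$mismatch_count,
                 skipped_loci = length(tt$skipped_loci), r = r_of(f),
                 si_excluded = excl, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[out$mismatch_count <= max_mismatch, , drop = FALSE]
    ord <- order(out$si_excluded, out$mismatch_count, -ifelse(is.na(out$r), -Inf, out$r),
                 out$candidate)
  } else {
    cand <- setdiff(ids, offspring)
    if (length(cand) < 2) stop("need at least two candidate parents")
    prs <- utils::combn(sort(cand), 2)
    rows <- lapply(seq_len(ncol(prs)), function(k) {
      m <- prs[1, k]; f <- prs[2, k]
      tt <- trio_test(table, offspring, m, f)
      excl <- !is.na(si_of(m)) && !is.na(si_of(f)) && si_of(m) == si_of(f)
      data.frame(mother = m, father = f,
                 mismatch_count = tt$mismatch_count,
                 skipped_loci = length(tt$skipped_loci),
                 r = mean(c(r_of(m), r_of(f)), na.rm = TRUE),
                 si_excluded = excl, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[out$mismatch_count <= max_mismatch, , drop = FALSE]
    ord <- order(out$si_excluded, out$mismatch_count, -ifelse(is.na(out$r), -Inf, out$r),
                 out$mother, out$father)
  }
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_ranking", "data.frame")
  out
}
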