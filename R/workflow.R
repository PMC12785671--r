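#' Run the full father-identification workflow
#'
#' Executes the complete analysis chain for a cultivar panel: codominant
#' distance matrix and neighbour-joining tree; all-dyads relatedness
#' matrix; kinship-category summary and relatedness-based UPGMA/Ward trees;
#' and, for each queried offspring, a candidate-father scan with Mendelian
#' trio testing and self-incompatibility exclusion. All artifacts are
#' written under `out_dir` together with a `manifest.txt` echoing every
#' setting (including the seed), so a run can be reproduced exactly.
#'
#' @param table A [genotype_table] (or path to a native CSV).
#' @param offspring Character vector of offspring ids to scan.
#' @param mother Optional known mother id (applied to every offspring).
#' @param si Optional SI data frame or path (see [read_si_csv()]); when
#'   absent, SI columns are reported as unavailable.
#' @param estimator Relatedness estimator for the dyad matrix.
#' @param thresholds Kinship cut points, see [category_thresholds()].
#' @param max_mismatch Mutation tolerance for the trio scan.
#' @param n_refs,seed Estimator settings.
#' @param out_dir Output directory (created if needed); `NULL` skips file
#'   output.
#' @return A `parentage_report`: list with `nj_tree`, `rmatrix`,
#'   `summary`, `heatmap`, per-offspring `rankings` and one-line
#'   `narratives`.
#' @export
run_full_workflow <- function(table, offspring, mother = NULL, si = NULL,
                              estimator = "dyadic_ml",
                              thresholds = category_thresholds(),
                              max_mismatch = 1, n_refs = 100, seed = 1,
                              out_dir = NULL) {
  if (is.character(table)) table <- read_genotype_csv(table)
  if (is.character(si)) si <- read_si_csv(si)
  if (!is.null(si)) table <- attach_si_groups(table, si)
  if (n_samples(table) < 3) stop("workflow needs at least 3 samples")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  dm <- stage("distance", codominant_distance(table))
  njt <- stage("nj_tree", neighbor_joining(dm))
  rmat <- stage("relatedness",
                relatedness_matrix(table, estimator, n_refs = n_refs,
                                   seed = seed))
  summ <- stage("classification", category_summary(rmat, thresholds))
  heat <- stage("heatmap", heatmap_matrix(rmat))
  rankings <- lapply(offspring, function(o)
    stage(paste0("scan_", o),
          scan_candidates(table, o, known_mother = mother,
                          max_mismatch = max_mismatch, si = si,
                          rmatrix = rmat)))
  names(rankings) <- offspring
  narratives <- vapply(offspring, function(o) {
    rk <- rankings[[o]]
    if (nrow(rk) == 0)
      return(sprintf("%s: no candidate within %d mismatches", o, max_mismatch))
    top <- rk[1, ]
    cand <- if ("candidate" %in% names(rk)) top$candidate
            else paste(top$mother, "x", top$father)
    sprintf("%s: top candidate %s (%d mismatching loci%s%s)", o, cand,
            top$mismatch_count,
            if (!is.na(top$r)) sprintf(", r = %.4f", top$r) else "",
            if (isTRUE(top$si_excluded)) ", SI-EXCLUDED" else
              if (is.null(si) && all(is.na(table$samples$si_group)))
                ", SI unavailable" else "")
  }, character(1))
  report <- structure(list(nj_tree = njt, rmatrix = rmat, summary = summ,
                           heatmap = heat, rankings = rankings,
                           narratives = narratives, seed = seed,
                           settings = list(estimator = estimator,
                                           thresholds = thresholds,
                                           max_mismatch = max_mismatch,
                                           n_refs = n_refs)),
                      class = "parentage_report")
  if (!is.null(out_dir)) write_report_artifacts(report, table, out_dir)
  report
}

#' @export
print.parentage_report <- function(x, ...) {
  cat("parentage report (seed ", x$seed, ")\n", sep = "")
  for (s in x$narratives) cat(" ", s, "\n")
  invisible(x)
}

write_report_artifacts <- function(report, table, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  manifest <- c(sprintf("seed=%d", report$seed),
                sprintf("estimator=%s", report$settings$estimator),
                sprintf("thresholds=%s",
                        paste(report$settings$thresholds, collapse = ",")),
                sprintf("max_mismatch=%d", report$settings$max_mismatch),
                sprintf("n_refs=%d", report$settings$n_refs),
                sprintf("n_samples=%d", n_samples(table)),
                sprintf("n_loci=%d", n_loci(table)))
  writeLines(manifest, p("manifest.txt"))
  write_newick(report$nj_tree, p("nj_tree.nwk"))
  utils::write.csv(report$rmatrix$dyads, p("dyads.csv"), row.names = FALSE)
  utils::write.csv(report$summary, p("summary.csv"), row.names = FALSE)
  rm <- report$heatmap$r_matrix
  utils::write.csv(data.frame(sample = rownames(rm), rm, check.names = FALSE),
                   p("r_matrix.csv"), row.names = FALSE)
  write_newick(report$heatmap$upgma_tree, p("heatmap_upgma.nwk"))
  write_newick(report$heatmap$ward_tree, p("heatmap_ward.nwk"))
  for (o in names(report$rankings))
    utils::write.csv(report$rankings[[o]],
                     p(sprintf("candidates_%s.csv", gsub("[^A-Za-z0-9_-]", "_", o))),
                     row.names = FALSE)
  writeLines(report$narratives, p("report.txt"))
  invisible(out_dir)
}
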