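#' Kinship categories and classification thresholds
#'
#' Dyads are binned into six kinship categories ordered by expected
#' relatedness: `unrelated` (r ~ 0), `second_cousin` (~ 1/32),
#' `first_cousin` (~ 1/8), `half_sib_uncle_grandparent` (~ 1/4),
#' `parent_child_full_sib` (~ 1/2) and `identity` (clones, r ~ 1). The
#' default cut points are midpoints between those canonical expectations
#' — `(0.016, 0.078, 0.1875, 0.39, 0.75)` — with the fourth raised from
#' 0.375 to 0.39 so that empirically observed half-sib-class values up to
#' 0.379 and parent-child-class values from 0.4003 both classify
#' correctly. Intervals are half-open, closed on the left, so a value
#' exactly at a cut point falls in the higher category.
#'
#' @return `kinship_categories()` returns the six category names in
#'   ascending order of expected r.
#' @export
kinship_categories <- function() {
  c("unrelated", "second_cousin", "first_cousin",
    "half_sib_uncle_grandparent", "parent_child_full_sib", "identity")
}

#' @rdname kinship_categories
#' @param thresholds Five strictly ascending cut points in (0, 1).
#' @export
category_thresholds <- function(thresholds = c(0.016, 0.078, 0.1875, 0.39, 0.75)) {
  if (length(thresholds) != 5) stop("exactly five cut points required")
  if (any(diff(thresholds) <= 0)) stop("cut points must strictly ascend")
  if (any(thresholds <= 0 | thresholds >= 1)) stop("cut points must lie in (0, 1)")
  thresholds
}

#' Classify relatedness values into kinship categories
#'
#' @param r Numeric vector of relatedness values. Values below 0 are
#'   clamped to 0 (moment estimates can undershoot); values above 1 are an
#'   error.
#' @param thresholds See [category_thresholds()].
#' @return Ordered factor over [kinship_categories()].
#' @export
classify_dyad <- function(r, thresholds = category_thresholds()) {
  thresholds <- category_thresholds(thresholds)
  if (any(!is.finite(r))) stop("r must be finite")
  if (any(r > 1 + 1e-9)) stop("r > 1 is not a valid relatedness value")
  r <- pmax(r, 0)
  idx <- findInterval(r, thresholds, left.open = FALSE) + 1L
  factor(kinship_categories()[idx], levels = kinship_categories(),
         ordered = TRUE)
}

#' Summarise the kinship-category composition of a dyad set
#'
#' `category_summary()` classifies every estimated dyad of a
#' [relatedness_matrix()] result; `summarise_category_counts()` applies the
#' same reporting rule to a precomputed count vector. Percentages are
#' `100 * count / total`, rounded half-up to two decimals.
#'
#' @param rmatrix A `relatedness_matrix`.
#' @param thresholds See [category_thresholds()].
#' @return Data frame with columns `category`, `count`, `percent`.
#' @export
category_summary <- function(rmatrix, thresholds = category_thresholds()) {
  r <- rmatrix$dyads$r
  if (all(is.na(r))) stop("no estimated dyads to summarise")
  cat <- classify_dyad(r[!is.na(r)], thresholds)
  counts <- as.integer(table(cat))
  names(counts) <- kinship_categories()
  summarise_category_counts(counts)
}

#' @rdname category_summary
#' @param counts Named or ordered integer vector of per-category counts
#'   (ascending category order).
#' @export
summarise_category_counts <- function(counts) {
  if (length(counts) != 6) stop("six category counts expected")
  total <- sum(counts)
  data.frame(category = factor(kinship_categories(),
                               levels = kinship_categories(), ordered = TRUE),
             count = as.integer(counts),
             percent = round_half_up(100 * counts / total, 2),
             row.names = NULL)
}

#' Heat-map matrix and relatedness-based trees
#'
#' Emits the symmetric relatedness matrix (diagonal set to 1: every
#' cultivar is its own clone), the derived dissimilarity `1 - r` (negative
#' moment estimates clamp the dissimilarity at 1, estimates above 1 at 0),
#' and rooted UPGMA and Ward dendrograms over that dissimilarity — the
#' computational content of a clustered relatedness heat map.
#'
#' @param rmatrix A `relatedness_matrix`.
#' @return List with `r_matrix`, `dist` (both named square matrices),
#'   `upgma_tree` and `ward_tree` (`phylo`).
#' @export
heatmap_matrix <- function(rmatrix) {
  r <- rmatrix$r
  diag(r) <- 1
  if (anyNA(r)) stop("heat map requires an estimate for every dyad")
  d <- pmin(pmax(1 - r, 0), 1)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  list(r_matrix = r, dist = d, upgma_tree = upgma(d), ward_tree = ward_cluster(d))
}

#' Long-format dyad records
#'
#' One row per unordered dyad with its relatedness, kinship category and
#' (when the table carries them) the SI groups of both members. Ids are
#' ordered lexicographically within each row.
#'
#' @param rmatrix A `relatedness_matrix`.
#' @param table Optional [genotype_table] supplying SI-group labels.
#' @param thresholds See [category_thresholds()].
#' @return Data frame `id1,id2,r,category,si_group1,si_group2`.
#' @export
dyad_records <- function(rmatrix, table = NULL,
                         thresholds = category_thresholds()) {
  d <- rmatrix$dyads
  rec <- data.frame(id1 = d$id1, id2 = d$id2, r = d$r,
                    category = classify_dyad(ifelse(is.na(d$r), 0, d$r),
                                             thresholds),
                    stringsAsFactors = FALSE)
  rec$category[is.na(d$r)] <- NA
  if (!is.null(table)) {
    si <- stats::setNames(table$samples$si_group, table$samples$sample)
    rec$si_group1 <- unname(si[rec$id1])
    rec$si_group2 <- unname(si[rec$id2])
  }
  rec
}
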