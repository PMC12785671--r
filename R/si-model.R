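#' Diallelic sporophytic self-incompatibility (DSI) model
#'
#' Olive self-incompatibility is controlled by a single S locus with two
#' alleles, S2 dominant over S1, giving exactly two incompatibility
#' phenotype groups: G1 (genotype S1S2) and G2 (genotype S1S1). Crosses are
#' incompatible within a group and compatible between groups. The S2S2
#' genotype is not observed in the field; the model maps it to phenotype G1
#' by S2 dominance and only produces it under pseudo-self-compatible
#' simulated crosses.
#'
#' @param g SI genotype string: `"S1S1"`, `"S1S2"` (or `"S2S1"`), `"S2S2"`.
#' @return `group_of()` returns `"G1"` or `"G2"`.
#' @export
group_of <- function(g) {
  vapply(g, function(x) {
    al <- parse_si_genotype(x)
    if ("S2" %in% al) "G1" else "G2"
  }, character(1), USE.NAMES = FALSE)
}

parse_si_genotype <- function(x) {
  al <- regmatches(x, gregexpr("S[12]", x))[[1]]
  if (length(al) != 2) stop("invalid S-locus genotype: ", x)
  sort(al)
}

#' @rdname group_of
#' @param mother,father SI group labels (`"G1"`/`"G2"`).
#' @return `cross_compatible()` returns `TRUE` iff the groups differ.
#' @export
cross_compatible <- function(mother, father) {
  stopifnot(mother %in% c("G1", "G2"), father %in% c("G1", "G2"))
  mother != father
}

#' Offspring SI-group distribution of a cross
#'
#' Enumerates the four equiprobable gamete pairs of the parental S-locus
#' genotypes and maps the resulting genotypes to phenotype groups.
#'
#' @param mother,father SI genotype strings (see [group_of()]).
#' @param allow_pseudo_self Permit within-group (normally incompatible)
#'   crosses, modelling pseudo-self-compatibility.
#' @return Named numeric vector `c(G1 = ..., G2 = ...)` summing to 1.
#' @export
offspring_group_distribution <- function(mother, father,
                                         allow_pseudo_self = FALSE) {
  gm <- parse_si_genotype(mother)
  gf <- parse_si_genotype(father)
  if (!cross_compatible(group_of(mother), group_of(father)) &&
      !allow_pseudo_self)
    stop("incompatible cross: both parents in SI group ", group_of(mother))
  combos <- expand.grid(m = gm, f = gf, stringsAsFactors = FALSE)
  groups <- group_of(paste0(combos$m, combos$f))
  p <- c(G1 = mean(groups == "G1"), G2 = mean(groups == "G2"))
  p
}

#' Paternity exclusion by SI group
#'
#' A candidate father in the same SI group as the mother is excluded: the
#' cross could not have occurred. The offspring's own group never excludes
#' a legitimate between-group cross, since both offspring groups are
#' possible from any compatible mating.
#'
#' @param mother_group,offspring_group,candidate_group SI group labels.
#' @return `"excluded"` or `"consistent"`.
#' @export
paternity_si_exclusion <- function(mother_group, offspring_group,
                                   candidate_group) {
  stopifnot(mother_group %in% c("G1", "G2"),
            candidate_group %in% c("G1", "G2"))
  if (candidate_group == mother_group) "excluded" else "consistent"
}

# Sample one gamete (S allele) from each parent; used by the simulator.
si_cross_offspring <- function(mother, father) {
  gm <- parse_si_genotype(mother)
  gf <- parse_si_genotype(father)
  paste0(sort(c(sample(gm, 1), sample(gf, 1))), collapse = "")
}

si_genotype_of_group <- function(group) {
  ifelse(group == "G1", "S1S2", "S1S1")
}
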