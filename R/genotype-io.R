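#' Read a diploid codominant genotype table from CSV
#'
#' Two dialects are supported. The `native` layout has a header
#' `sample,population,si_group,<locus>_a,<locus>_b,...` with one row per
#' sample; `population` and `si_group` may be blank. The `genalex` layout is
#' the GenAlEx codominant export: a first row of counts
#' (`n_loci,n_samples,n_pops,...`), a second row with a title cell followed by
#' locus names (one per pair of allele columns), then one row per sample of
#' `sample,population,allele,allele,...`. In both dialects missing data are
#' written as `0` (GenAlEx convention) or left blank, and are read back as
#' `NA`; allele pairs are stored in canonical order.
#'
#' @param path Path to a CSV file.
#' @param dialect `"native"` or `"genalex"`.
#' @return A [genotype_table].
#' @export
read_genotype_csv <- function(path, dialect = c("native", "genalex")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (dialect == "native") read_native_csv(path) else read_genalex_csv(path)
}

check_rectangular <- function(path, skip = 0) {
  nf <- utils::count.fields(path, sep = ",", comment.char = "#", quote = "\"")
  nf <- nf[!is.na(nf)]
  if (skip > 0) nf <- nf[-seq_len(skip)]
  if (length(nf) > 1 && length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1] + skip
    stop("ragged row in ", path, ": line ", bad, " has ", nf[bad - skip],
         " fields, expected ", nf[1])
  }
}

parse_allele <- function(x) {
  x <- trimws(as.character(x))
  x[x == "" | x == "0" | is.na(x)] <- NA
  v <- suppressWarnings(as.integer(x))
  if (any(is.na(v) & !is.na(x))) stop("non-integer allele value: ", x[is.na(v) & !is.na(x)][1])
  v
}

read_native_csv <- function(path) {
  check_rectangular(path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        comment.char = "#")
  if (nrow(df) == 0) stop("empty table body in ", path)
  need <- c("sample", "population", "si_group")
  if (!all(need %in% names(df)))
    stop("native dialect requires header columns: ", paste(need, collapse = ", "))
  locus_cols <- setdiff(names(df), need)
  a_cols <- grep("_a$", locus_cols, value = TRUE)
  loci <- sub("_a$", "", a_cols)
  if (!all(paste0(loci, "_b") %in% locus_cols))
    stop("each locus needs paired <locus>_a and <locus>_b columns")
  a <- sapply(paste0(loci, "_a"), function(cl) parse_allele(df[[cl]]))
  b <- sapply(paste0(loci, "_b"), function(cl) parse_allele(df[[cl]]))
  if (nrow(df) == 1) { a <- matrix(a, 1); b <- matrix(b, 1) }
  blank_to_na <- function(v) { v <- trimws(v); v[v == ""] <- NA; v }
  genotype_table(a, b,
                 data.frame(sample = df$sample,
                            population = blank_to_na(df$population),
                            si_group = blank_to_na(df$si_group)),
                 data.frame(locus = loci))
}

read_genalex_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("empty table body in ", path)
  check_rectangular(path, skip = 0)
  hdr <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  loci <- hdr[seq(3, length(hdr), by = 2)]
  loci <- loci[loci != ""]
  body <- utils::read.csv(text = paste(lines[-(1:2)], collapse = "\n"),
                          header = FALSE, colClasses = "character")
  if (nrow(body) == 0) stop("empty table body in ", path)
  if (ncol(body) != 2 + 2 * length(loci))
    stop("genalex body has ", ncol(body), " columns, expected ", 2 + 2 * length(loci))
  a <- sapply(seq_along(loci), function(l) parse_allele(body[[2 * l + 1]]))
  b <- sapply(seq_along(loci), function(l) parse_allele(body[[2 * l + 2]]))
  if (nrow(body) == 1) { a <- matrix(a, 1); b <- matrix(b, 1) }
  pop <- trimws(body[[2]]); pop[pop == ""] <- NA
  genotype_table(a, b,
                 data.frame(sample = trimws(body[[1]]), population = pop),
                 data.frame(locus = loci))
}

#' Write a genotype table to CSV
#'
#' `write_genotype_csv()` writes the native layout (including `si_group`);
#' `write_genalex()` writes the GenAlEx codominant layout, which carries
#' sample, population and calls but no SI labels. Missing calls are written
#' as `0` in both dialects. Both round-trip through [read_genotype_csv()].
#'
#' @param table A [genotype_table].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_genotype_csv <- function(table, path) {
  enc <- function(m) { m[is.na(m)] <- 0L; m }
  a <- enc(table$a); b <- enc(table$b)
  df <- data.frame(sample = table$samples$sample,
                   population = ifelse(is.na(table$samples$population), "",
                                       table$samples$population),
                   si_group = ifelse(is.na(table$samples$si_group), "",
                                     table$samples$si_group),
                   check.names = FALSE)
  for (l in seq_len(ncol(a))) {
    df[[paste0(table$loci$locus[l], "_a")]] <- a[, l]
    df[[paste0(table$loci$locus[l], "_b")]] <- b[, l]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotype_csv
#' @export
write_genalex <- function(table, path) {
  n <- nrow(table$a); L <- ncol(table$a)
  ncols <- 2 + 2 * L
  pad <- function(cells) {
    c(cells, rep("", ncols - length(cells)))
  }
  row1 <- pad(c(L, n, 1, n))
  hdr <- character(2 * L)
  hdr[seq(1, 2 * L, 2)] <- table$loci$locus
  row2 <- pad(c("olivekin export", "", hdr))[1:ncols]
  enc <- function(m) { m[is.na(m)] <- 0L; m }
  a <- enc(table$a); b <- enc(table$b)
  body <- matrix("", n, ncols)
  body[, 1] <- table$samples$sample
  body[, 2] <- ifelse(is.na(table$samples$population), "1",
                      table$samples$population)
  for (l in seq_len(L)) {
    body[, 2 * l + 1] <- a[, l]
    body[, 2 * l + 2] <- b[, l]
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste(row1, collapse = ","), paste(row2, collapse = ","),
               apply(body, 1, paste, collapse = ",")), con)
  invisible(path)
}

#' Read SI-group labels from CSV
#'
#' Expects columns `sample,si_group` with values `G1`/`G2`. Lines starting
#' with `#` are treated as comments.
#'
#' @param path Path to a CSV file.
#' @return Data frame with columns `sample`, `si_group`.
#' @export
read_si_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", colClasses = "character")
  if (!all(c("sample", "si_group") %in% names(df)))
    stop("SI file requires columns sample,si_group")
  bad <- setdiff(unique(df$si_group), c("G1", "G2"))
  if (length(bad)) stop("invalid SI group label: ", bad[1])
  df[c("sample", "si_group")]
}

#' Attach SI-group labels to a genotype table
#'
#' @param table A [genotype_table].
#' @param si Data frame as returned by [read_si_csv()].
#' @return The table with `si_group` filled for matching samples.
#' @export
attach_si_groups <- function(table, si) {
  i <- match(table$samples$sample, si$sample)
  table$samples$si_group <- ifelse(is.na(i), table$samples$si_group,
                                   si$si_group[i])
  table
}
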