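#' Build a genotype table
#'
#' The central genotype container is a long tibble with one row per individual
#' x locus: columns `individual`, `locus`, `allele_1`, `allele_2`. Diploid
#' calls are unordered pairs of opaque allele symbols; a missing genotype has
#' `NA` in both allele columns. The pair is stored in canonical (sorted)
#' order so that equality of calls is equality of rows.
#'
#' @param individual,locus character vectors.
#' @param allele_1,allele_2 character vectors of allele symbols (`NA` = missing).
#' @return A tibble of class `genotype_tbl`.
#' @export
genotype_table <- function(individual, locus, allele_1, allele_2) {
  tbl <- tibble::tibble(
    individual = as.character(individual),
    locus = as.character(locus),
    allele_1 = as.character(allele_1),
    allele_2 = as.character(allele_2)
  )
  # half-missing calls carry no usable phase-free information: drop to missing
  half <- xor(is.na(tbl$allele_1), is.na(tbl$allele_2))
  if (any(half)) {
    warn(sprintf("%d half-missing calls set to missing", sum(half)))
    tbl$allele_1[half] <- NA_character_
    tbl$allele_2[half] <- NA_character_
  }
  swap <- !is.na(tbl$allele_1) & tbl$allele_2 < tbl$allele_1
  if (any(swap)) {
    tmp <- tbl$allele_1[swap]
    tbl$allele_1[swap] <- tbl$allele_2[swap]
    tbl$allele_2[swap] <- tmp
  }
  if (anyDuplicated(tbl[c("individual", "locus")]) > 0) {
    abort("duplicate individual x locus entries in genotype table")
  }
  class(tbl) <- c("genotype_tbl", class(tbl))
  tbl
}

#' @export
#' @rdname genotype_table
#' @param x object to validate.
validate_genotype_table <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("individual", "locus", "allele_1", "allele_2")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste("genotype table missing columns:", paste(miss, collapse = ", ")))
  bad <- xor(is.na(x$allele_1), is.na(x$allele_2))
  if (any(bad)) abort("half-missing genotype calls present")
  invisible(x)
}

genotype_individuals <- function(g) unique(g$individual)
genotype_loci <- function(g) unique(g$locus)

#' Read a diploid genotype table
#'
#' Two dialects are supported:
#' * `"wide_csv"`: a CSV with an `individual` column followed by two columns
#'   per locus named `<locus>_1` and `<locus>_2`.
#' * `"structure"`: whitespace-delimited, two rows per individual (one allele
#'   row per chromosome copy), first token the individual id, optionally
#'   preceded by a header row of locus names.
#'
#' Missing-data codes are normalized to `NA`; the symbol table observed per
#' locus is attached as attribute `"alleles"`.
#'
#' @param path file path.
#' @param dialect `"wide_csv"` or `"structure"`.
#' @param missing_codes character vector of symbols to read as missing.
#' @return A `genotype_tbl`.
#' @export
read_genotype_table <- function(path, dialect = c("wide_csv", "structure"),
                                missing_codes = c("", "NA", "-9", "?")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste("no such file:", path))
  g <- switch(dialect,
    wide_csv = read_genotype_wide_csv(path, missing_codes),
    structure = read_genotype_structure(path, missing_codes)
  )
  attr(g, "alleles") <- g |>
    dplyr::filter(!is.na(.data$allele_1)) |>
    tidyr::pivot_longer(c("allele_1", "allele_2"), values_to = "allele") |>
    dplyr::distinct(.data$locus, .data$allele) |>
    dplyr::arrange(.data$locus, .data$allele)
  g
}

read_genotype_wide_csv <- function(path, missing_codes) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (!"individual" %in% names(df)) abort("wide_csv dialect requires an 'individual' column")
  cols <- setdiff(names(df), "individual")
  stem <- sub("_[12]$", "", cols)
  copy <- sub("^.*_([12])$", "\\1", cols)
  if (any(copy %in% c("1", "2") == FALSE)) {
    abort(paste("columns not named <locus>_1/<locus>_2:",
                paste(cols[!copy %in% c("1", "2")], collapse = ", ")))
  }
  loci <- unique(stem)
  for (l in loci) {
    if (sum(stem == l) != 2) abort(paste("locus", l, "does not have exactly two allele columns"))
  }
  long <- df |>
    tidyr::pivot_longer(-"individual", names_to = c("locus", "copy"),
                        names_pattern = "^(.*)_([12])$", values_to = "allele") |>
    tidyr::pivot_wider(names_from = "copy", values_from = "allele", names_prefix = "allele_")
  long$allele_1[long$allele_1 %in% missing_codes] <- NA
  long$allele_2[long$allele_2 %in% missing_codes] <- NA
  genotype_table(long$individual, long$locus, long$allele_1, long$allele_2)
}

read_genotype_structure <- function(path, missing_codes) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty genotype file")
  toks <- strsplit(trimws(lines), "\\s+")
  n_tok <- lengths(toks)
  body_width <- max(n_tok)
  header <- NULL
  if (n_tok[1] == body_width - 1L) {  # header row of locus names
    header <- toks[[1]]
    toks <- toks[-1]
    n_tok <- n_tok[-1]
  }
  bad <- which(n_tok != body_width)
  if (length(bad)) {
    abort(sprintf("ragged genotype rows (line %d has %d fields, expected %d)",
                  bad[1] + ifelse(is.null(header), 0L, 1L), n_tok[bad[1]], body_width))
  }
  if (length(toks) %% 2L != 0L) abort("structure dialect needs two rows per individual")
  n_loci <- body_width - 1L
  loci <- header %||% sprintf("L%03d", seq_len(n_loci))
  row1 <- toks[seq(1, length(toks), by = 2)]
  row2 <- toks[seq(2, length(toks), by = 2)]
  ids1 <- vapply(row1, `[[`, "", 1L)
  ids2 <- vapply(row2, `[[`, "", 1L)
  if (!all(ids1 == ids2)) abort("paired rows disagree on individual id")
  a1 <- do.call(rbind, lapply(row1, function(x) x[-1]))
  a2 <- do.call(rbind, lapply(row2, function(x) x[-1]))
  a1[a1 %in% missing_codes] <- NA
  a2[a2 %in% missing_codes] <- NA
  genotype_table(
    individual = rep(ids1, each = n_loci),
    locus = rep(loci, times = length(ids1)),
    allele_1 = as.vector(t(a1)),
    allele_2 = as.vector(t(a2))
  )
}

#' Write a genotype table (wide CSV dialect)
#'
#' @param g a `genotype_tbl`.
#' @param path output path.
#' @param missing_code symbol written for missing calls.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(g, path, missing_code = "") {
  validate_genotype_table(g)
  wide <- g |>
    tidyr::pivot_longer(c("allele_1", "allele_2"), names_to = "copy",
                        names_pattern = "allele_([12])", values_to = "allele") |>
    dplyr::mutate(col = paste0(.data$locus, "_", .data$copy)) |>
    dplyr::select("individual", "col", "allele") |>
    tidyr::pivot_wider(names_from = "col", values_from = "allele") |>
    dplyr::arrange(.data$individual)
  wide[is.na(wide)] <- missing_code
  write_results_table(wide, path)
}
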