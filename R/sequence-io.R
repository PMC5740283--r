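#' Read an aligned FASTA file into a sequence tibble
#'
#' Sequences are returned upper-cased in a tibble with columns `id` and `seq`.
#' Within one set all sequences must be the same (aligned) length and use the
#' alphabet `A C G T N -`.
#'
#' @param path FASTA file.
#' @param require_aligned error if lengths differ (default `TRUE`).
#' @return tibble with columns `id`, `seq`, plus attribute `"length"`.
#' @export
read_fasta <- function(path, require_aligned = TRUE) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty FASTA file")
  hdr <- grepl("^>", lines)
  if (!hdr[1]) abort("not a FASTA file (no leading '>')")
  id <- sub("^>\\s*", "", lines[hdr])
  id <- sub("\\s.*$", "", id)  # keep first token of the header
  if (anyDuplicated(id)) {
    abort(paste("duplicate FASTA headers:", paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  if (length(seqs) != length(id)) abort("FASTA record without sequence lines")
  seqs <- toupper(gsub("\\s", "", unname(seqs)))
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) abort(paste("non-ACGTN- symbols in sequences:", paste(id[bad], collapse = ", ")))
  len <- nchar(seqs)
  if (require_aligned && length(unique(len)) > 1) {
    abort("sequences are not aligned (unequal lengths)")
  }
  out <- tibble::tibble(id = id, seq = seqs)
  attr(out, "length") <- if (length(unique(len)) == 1) len[1] else NA_integer_
  out
}

#' Write a sequence tibble as FASTA
#'
#' @param seqs tibble with columns `id`, `seq`.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$id[i]), con)
    s <- seqs$seq[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write a results table as a deterministic CSV
#'
#' Rows are sorted on the first column (locality/individual id order), floats
#' are written at fixed precision, so two runs on the same input produce
#' byte-identical files.
#'
#' @param records a data frame; all rows share one schema.
#' @param path output path.
#' @param digits decimal places for numeric columns.
#' @param sort_by column to sort on (default: first column).
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path, digits = 6, sort_by = NULL) {
  if (!is.data.frame(records)) {
    if (is.list(records)) {
      schemas <- unique(lapply(records, names))
      if (length(schemas) > 1) abort("records do not share a single schema")
      records <- dplyr::bind_rows(records)
    } else {
      abort("records must be a data frame or list of records")
    }
  }
  df <- as.data.frame(records)
  if (nrow(df) > 0) {
    key <- sort_by %||% names(df)[1]
    df <- df[order(df[[key]]), , drop = FALSE]
  }
  cells <- lapply(df, function(col) {
    out <- if (is.double(col)) {
      ifelse(is.na(col), "", formatC(col, digits = digits, format = "f"))
    } else {
      ifelse(is.na(col), "", as.character(col))
    }
    # quote fields containing separators
    needs <- grepl('[",\n]', out)
    out[needs] <- paste0('"', gsub('"', '""', out[needs]), '"')
    out
  })
  if (nrow(df) == 0) {
    lines <- paste(names(df), collapse = ",")
  } else {
    cells <- do.call(cbind, cells)
    lines <- c(paste(names(df), collapse = ","),
               apply(cells, 1, paste, collapse = ","))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path CSV path.
#' @return tibble.
#' @export
read_results_table <- function(path) {
  tibble::as_tibble(read.csv(path, check.names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
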