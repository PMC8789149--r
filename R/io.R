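#' Read a numeric matrix from CSV or TSV
#'
#' Reads a delimited numeric matrix. The delimiter is taken from the
#' file extension (`.tsv`/`.tab` means tab, anything else comma). A
#' single header row is auto-detected: if any field of the first row is
#' non-numeric it is treated as column names. Ragged files and
#' non-numeric cells are reported with their row (and column) numbers.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  nf <- count.fields(path, sep = sep, blank.lines.skip = TRUE)
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged file '%s': row %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1]))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, sep, fixed = TRUE)
  first <- suppressWarnings(as.numeric(fields[[1L]]))
  header <- anyNA(first)
  cn <- if (header) trimws(fields[[1L]]) else NULL
  body <- if (header) fields[-1L] else fields
  if (length(body) == 0) stop("no data rows in ", path)
  vals <- suppressWarnings(lapply(body, as.numeric))
  for (i in seq_along(vals)) {
    if (anyNA(vals[[i]]) && !all(trimws(body[[i]][is.na(vals[[i]])]) %in%
                                 c("NA", "nan", "NaN"))) {
      j <- which(is.na(vals[[i]]))[1]
      stop(sprintf("non-numeric cell in '%s' at row %d, column %d: '%s'",
                   path, i + header, j, body[[i]][j]))
    }
  }
  M <- do.call(rbind, vals)
  colnames(M) <- cn
  M
}

#' Write a numeric matrix as headerless CSV
#'
#' @param x numeric matrix.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  # 17 significant digits round-trips doubles exactly
  fmt <- matrix(sprintf("%.17g", x), nrow(x), ncol(x))
  write.table(fmt, path, sep = ",", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Write an edge list from an adjacency or weight matrix
#'
#' Writes the nonzero strict-upper-triangle entries as a 3-column TSV
#' `i`, `j`, `weight` with 1-based indices and a header row. For a
#' binary adjacency the weight column is 1; pass a weight matrix (e.g.
#' `delta_sparse`) to record magnitudes.
#'
#' @param M square matrix (adjacency or weights).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_edges <- function(M, path) {
  idx <- which(upper.tri(M) & M != 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], weight = M[idx])
  df <- df[order(df$i, df$j), , drop = FALSE]
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records a run configuration (plus package and R versions) so the run
#' can be reproduced exactly.
#'
#' @param config named list of configuration values (should include the
#'   seed).
#' @param path destination `.json` file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  config$package <- as.character(packageVersion("bdnet"))
  config$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
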