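# TSV readers/writers for the interchange formats: edge lists, expression
# matrices, dense symmetric matrices, ID lists.  Tab-delimited, '.' decimal
# separator, no quoting; gzip accepted transparently on read.  Numbers are
# written with 17 significant digits so write/read round-trips are exact and
# a second write reproduces the first byte-for-byte.

fmt_num <- function(x) sprintf("%.17g", x)

#' Read a regulator-gene edge list
#'
#' Three tab-separated columns: regulator ID, gene ID, numeric weight.
#'
#' @param path Path to a TSV file (gzip accepted).
#' @param header Whether the file has a header row; default `FALSE`.
#' @return Tibble with columns `regulator`, `gene`, `weight`.
#' @export
read_edge_list <- function(path, header = FALSE) {
  cn <- if (header) TRUE else c("regulator", "gene", "weight")
  df <- suppressWarnings(   # parse issues surface via problems() below
    readr::read_tsv(path, col_names = cn, col_types = "ccc",
                    progress = FALSE, show_col_types = FALSE))
  if (ncol(df) != 3) {
    abort(sprintf("read_edge_list: expected 3 columns in %s, found %d", path, ncol(df)))
  }
  names(df) <- c("regulator", "gene", "weight")
  # numeric conversion through base R for an exact (1-ulp-free) round trip
  df$weight <- suppressWarnings(as.numeric(df$weight))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("read_edge_list: malformed row at line %d of %s (%s)",
                  probs$row[1] + as.integer(header), path, probs$expected[1]))
  }
  if (any(!is.finite(df$weight))) {
    bad <- which(!is.finite(df$weight))[1]
    abort(sprintf("read_edge_list: non-numeric weight at line %d of %s",
                  bad + as.integer(header), path))
  }
  dup <- duplicated(df[, c("regulator", "gene")])
  if (any(dup)) {
    bad <- which(dup)[1]
    abort(sprintf("read_edge_list: duplicate (regulator, gene) pair '%s, %s' at line %d of %s",
                  df$regulator[bad], df$gene[bad], bad + as.integer(header), path))
  }
  df
}

#' Write a regulator-gene edge list
#'
#' @param edges Tibble with columns `regulator`, `gene`, `weight`.
#' @param path Output path.
#' @param header Whether to write a header row; default `FALSE`.
#' @export
write_edge_list <- function(edges, path, header = FALSE) {
  stopifnot(all(c("regulator", "gene", "weight") %in% names(edges)))
  lines <- paste(edges$regulator, edges$gene, fmt_num(edges$weight), sep = "\t")
  if (header) lines <- c("regulator\tgene\tweight", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix
#'
#' First column gene ID, remaining columns per-sample values, header row of
#' sample IDs.
#'
#' @param path Path to a TSV file (gzip accepted).
#' @return Tibble with a `gene` column followed by sample columns.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("read_expression: malformed row at line %d of %s",
                  probs$row[1] + 1L, path))
  }
  names(df)[1] <- "gene"
  for (j in seq_along(df)[-1]) {
    v <- suppressWarnings(as.numeric(df[[j]]))   # base parse: exact round trip
    if (any(is.na(v) & !is.na(df[[j]]))) {
      bad <- which(is.na(v) & !is.na(df[[j]]))[1]
      abort(sprintf("read_expression: non-numeric value '%s' at line %d of %s",
                    df[[j]][bad], bad + 1L, path))
    }
    df[[j]] <- v
  }
  if (anyDuplicated(df$gene)) {
    abort(sprintf("read_expression: duplicate gene ID '%s' in %s",
                  df$gene[duplicated(df$gene)][1], path))
  }
  df
}

#' Write an expression matrix
#'
#' @param expression Tibble with `gene` column followed by sample columns.
#' @param path Output path.
#' @export
write_expression <- function(expression, path) {
  vals <- as.matrix(expression[, -1, drop = FALSE])
  lines <- c(paste(c("gene", colnames(vals)), collapse = "\t"),
             paste(expression[[1]],
                   apply(vals, 1, function(r) paste(fmt_num(r), collapse = "\t")),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a dense labelled matrix (e.g. regulator cooperativity)
#'
#' Tab-separated with an ID header row and an ID first column.
#'
#' @param path Path to a TSV file (gzip accepted).
#' @return A numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- read_expression(path)
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- df$gene
  M
}

#' Write a dense labelled matrix
#'
#' @param M Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix <- function(M, path) {
  lines <- c(paste(c("id", colnames(M)), collapse = "\t"),
             paste(rownames(M),
                   apply(M, 1, function(r) paste(fmt_num(r), collapse = "\t")),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ID list (one ID per line)
#'
#' @param path Path to a text file (gzip accepted).
#' @return Character vector of IDs.
#' @export
read_id_list <- function(path) {
  ids <- trimws(readr::read_lines(path))
  ids[nzchar(ids)]
}
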