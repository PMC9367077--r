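# Reading and writing the package's tabular interchange formats.

#' Read a two-column edge list from a TSV file
#'
#' Accepts an optional header line. Rows that do not contain exactly two
#' non-empty identifier fields are rejected with their line numbers.
#'
#' @param path Path to a tab-separated file with two identifier columns.
#' @param header Does the file carry a header line? Default `FALSE`.
#' @return A data frame with columns `from` and `to`.
#' @export
read_edge_tsv <- function(path, header = FALSE) {
  lines <- readLines(path)
  if (header && length(lines) > 0) lines <- lines[-1]
  lines_nonempty <- which(nzchar(trimws(lines)))
  fields <- strsplit(lines[lines_nonempty], "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) length(f) == 2L && all(nzchar(trimws(f))),
               logical(1))
  if (!all(ok)) {
    bad <- lines_nonempty[!ok] + as.integer(header)
    stop(sprintf("malformed edge rows (need exactly 2 id columns) at line(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  data.frame(
    from = trimws(vapply(fields, `[[`, "", 1L)),
    to = trimws(vapply(fields, `[[`, "", 2L)),
    stringsAsFactors = FALSE
  )
}

#' Write a two-column edge list as TSV
#'
#' @param edges Data frame whose first two columns are identifiers.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_tsv <- function(edges, path) {
  write.table(edges[, 1:2], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an embedding matrix as TSV
#'
#' Columns: `node_id`, `kind` (if known), `v1`..`vk`.
#'
#' @param emb An embedding matrix (rownames are node ids).
#' @param path Output path.
#' @param kinds Optional named character vector mapping node id to kind.
#' @return Invisibly, `path`.
#' @export
write_embedding_tsv <- function(emb, path, kinds = NULL) {
  df <- data.frame(node_id = rownames(emb), stringsAsFactors = FALSE)
  if (!is.null(kinds)) df$kind <- unname(kinds[df$node_id])
  colnames(emb) <- paste0("v", seq_len(ncol(emb)))
  df <- cbind(df, as.data.frame(emb, row.names = NULL))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an embedding matrix written by [write_embedding_tsv()] or in the
#' word2vec text format
#'
#' @param path Path to a TSV with a `node_id` column (package format) or a
#'   whitespace-separated word2vec text file whose first line is
#'   `<n> <dim>`.
#' @return A numeric matrix with node ids as rownames.
#' @export
read_embedding_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^\\d+\\s+\\d+\\s*$", first)) {
    # word2vec text format
    tab <- read.table(path, skip = 1L, header = FALSE,
                      stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    colnames(m) <- NULL
    return(m)
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  vcols <- grep("^v\\d+$", names(tab))
  m <- as.matrix(tab[, vcols, drop = FALSE])
  rownames(m) <- tab$node_id
  colnames(m) <- NULL
  m
}
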