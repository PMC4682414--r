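#' Read a feature-by-sample matrix from TSV
#'
#' First column is the feature id, remaining columns are samples. Comment
#' lines starting with `#` are skipped.
#'
#' @param path TSV file path.
#' @return a numeric matrix with feature ids as rownames.
#' @export
read_matrix_tsv <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  m <- as.matrix(tbl[, -1])
  rownames(m) <- tbl[[1]]
  storage.mode(m) <- "double"
  m
}

write_matrix_tsv <- function(m, path, id_col) {
  tbl <- tibble::as_tibble(m, rownames = id_col)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read / write gene-set collections in GMT format
#'
#' GMT is tab-separated: term id, description, then member genes. Reading
#' delegates to `fgsea::gmtPathways()` when fgsea is installed and falls
#' back to a line parser otherwise; descriptions are not retained.
#'
#' @param path GMT file path.
#' @return named list of character vectors (term id -> member genes).
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(purrr::map(parts, ~ .x[-(1:2)]),
                  purrr::map_chr(parts, 1))
}

#' @param terms named list of character vectors.
#' @param descriptions optional character vector parallel to `terms`.
#' @rdname read_gmt
#' @export
write_gmt <- function(terms, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(terms))
  lines <- purrr::map_chr(seq_along(terms), function(i) {
    paste(c(names(terms)[i], descriptions[i], terms[[i]]), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' @noRd
#' TSV writer that prefixes reproducibility metadata as comment lines.
write_tsv_stamped <- function(tbl, path, stamp = NULL) {
  if (!is.null(stamp)) {
    writeLines(paste0("# ", stamp), path)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(tbl, path)
  }
  invisible(path)
}
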