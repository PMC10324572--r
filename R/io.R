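#' Read and write OTU count tables
#'
#' `read_counts_table()` reads a tab-separated OTU table (one header row of
#' sample ids, first column of taxon ids) or a BIOM 1.0 JSON file, validates
#' it, and returns a [community_matrix()]. `write_counts_table()` writes the
#' canonical TSV layout (taxa in rows).
#'
#' @param path file path.
#' @param orientation whether rows of the TSV are taxa (`"taxa_rows"`,
#'   default) or samples (`"samples_rows"`).
#' @param format `"tsv"` or `"biom"`; guessed from the file extension by
#'   default. The BIOM reader requires the `biomformat` package.
#' @return A [community_matrix()].
#' @export
read_counts_table <- function(path, orientation = c("taxa_rows", "samples_rows"),
                              format = c("auto", "tsv", "biom")) {
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.biom$|\\.json$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("reading BIOM files requires the `biomformat` package.")
    }
    m <- as.matrix(biomformat::biom_data(biomformat::read_biom(path)))
    return(as_community_matrix(m, orientation = orientation))
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort(sprintf("'%s' does not look like an id + counts TSV.", path))
  for (j in 2:ncol(df)) {
    if (!is.numeric(df[[j]])) {
      abort(sprintf("non-numeric cells in column '%s' of '%s'.", names(df)[j], path))
    }
  }
  as_community_matrix(df, taxa_col = 1L, orientation = orientation)
}

#' @rdname read_counts_table
#' @param cm a [community_matrix()] (or coercible).
#' @param id_header header for the taxon-id column (default `"taxon_id"`).
#' @export
write_counts_table <- function(cm, path, id_header = "taxon_id") {
  m <- as_counts_matrix(cm)
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_header
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Reads a metadata TSV with at least the columns `sample_id`, `salinity`,
#' `habitat` and `group`; any further numeric columns (e.g. nutrient
#' concentrations in uM) are kept. Validates uniqueness of sample ids,
#' non-negativity of salinity, and consistency of `group` with `habitat`
#' (a group label containing "water"/"sediment" must match the habitat).
#'
#' @param path file path to a tab-separated metadata table.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  md <- as_tibble(utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE))
  validate_sample_metadata(md)
}

#' @rdname read_sample_metadata
#' @param md a data frame of sample metadata.
#' @export
validate_sample_metadata <- function(md) {
  need <- c("sample_id", "salinity", "habitat", "group")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols)) {
    abort(sprintf("metadata is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(md$sample_id)) abort("duplicate sample_id in metadata.")
  if (any(md$salinity < 0, na.rm = TRUE)) abort("negative salinity in metadata.")
  num <- vapply(md, is.numeric, logical(1))
  for (v in names(md)[num]) {
    if (v != "salinity" && any(md[[v]] < 0, na.rm = TRUE)) {
      abort(sprintf("negative values in metadata column '%s'.", v))
    }
  }
  bad <- (grepl("water", md$group) & md$habitat != "water") |
    (grepl("sediment", md$group) & md$habitat != "sediment")
  if (any(bad)) {
    abort(sprintf("group label inconsistent with habitat for sample(s): %s",
                  paste(md$sample_id[bad], collapse = ", ")))
  }
  as_tibble(md)
}

#' @rdname read_sample_metadata
#' @export
write_sample_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
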