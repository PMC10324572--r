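#' Community count matrix
#'
#' The central data container: a taxa x samples table of non-negative integer
#' read counts, with optional taxonomy strings per taxon. All analysis
#' functions in the package accept a `community_matrix`, a plain matrix with
#' dimnames, or a data frame with taxa in the first column.
#'
#' @param counts numeric matrix of non-negative integers, taxa in rows and
#'   samples in columns, with unique `rownames` (taxon ids) and `colnames`
#'   (sample ids).
#' @param taxonomy optional named character vector mapping taxon id to a
#'   lineage string.
#' @return An object of class `community_matrix`: a list with elements
#'   `counts` (integer matrix) and `taxonomy`.
#' @examples
#' m <- matrix(c(5L, 3L, 0L, 2L), 2, 2,
#'   dimnames = list(c("otu1", "otu2"), c("s1", "s2")))
#' community_matrix(m)
#' @export
community_matrix <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) abort("`counts` must be a matrix (taxa x samples).")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have rownames (taxon ids) and colnames (sample ids).")
  }
  if (anyDuplicated(rownames(counts))) abort("duplicate taxon ids in `counts`.")
  if (anyDuplicated(colnames(counts))) abort("duplicate sample ids in `counts`.")
  if (any(is.na(counts))) abort("`counts` contains missing values.")
  if (any(counts < 0)) abort("`counts` contains negative values.")
  if (any(counts != round(counts))) abort("`counts` contains non-integer values.")
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[intersect(names(taxonomy), rownames(counts))]
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "community_matrix")
}

#' Coerce to a community matrix
#'
#' @param x a `community_matrix`, an integer matrix (taxa x samples by
#'   default), or a data frame whose first column (or `taxa_col`) holds taxon
#'   ids and whose remaining numeric columns are samples.
#' @param orientation `"taxa_rows"` (default) or `"samples_rows"`; the latter
#'   transposes on the way in.
#' @param taxa_col for data-frame input, the column holding taxon ids.
#' @param ... passed on to methods.
#' @return A [community_matrix()].
#' @export
as_community_matrix <- function(x, ...) UseMethod("as_community_matrix")

#' @rdname as_community_matrix
#' @export
as_community_matrix.community_matrix <- function(x, ...) x

#' @rdname as_community_matrix
#' @export
as_community_matrix.matrix <- function(x, orientation = c("taxa_rows", "samples_rows"), ...) {
  orientation <- match.arg(orientation)
  if (orientation == "samples_rows") x <- t(x)
  community_matrix(x)
}

#' @rdname as_community_matrix
#' @export
as_community_matrix.data.frame <- function(x, taxa_col = 1L,
                                           orientation = c("taxa_rows", "samples_rows"),
                                           ...) {
  orientation <- match.arg(orientation)
  ids <- as.character(x[[taxa_col]])
  m <- as.matrix(x[setdiff(seq_along(x), if (is.numeric(taxa_col)) taxa_col else match(taxa_col, names(x)))])
  if (!is.numeric(m)) abort("non-numeric cells in count table.")
  rownames(m) <- ids
  if (orientation == "samples_rows") m <- t(m)
  community_matrix(m)
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("<community_matrix> %d taxa x %d samples, %s reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.community_matrix <- function(x) dim(x$counts)

#' Axis identifiers of a community matrix
#' @param cm a [community_matrix()] (or coercible).
#' @return Character vector of ids.
#' @export
taxon_ids <- function(cm) rownames(as_counts_matrix(cm))

#' @rdname taxon_ids
#' @export
sample_ids <- function(cm) colnames(as_counts_matrix(cm))

#' @describeIn community_matrix long-format tibble (taxon_id, sample_id, count).
#' @param x a `community_matrix`.
#' @param ... unused.
#' @export
as_tibble.community_matrix <- function(x, ...) {
  m <- x$counts
  tibble(
    taxon_id = rep(rownames(m), times = ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    count = as.integer(m)
  )
}
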