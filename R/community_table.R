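#' Construct a community table
#'
#' A community table is the central container of the pipeline: a non-negative
#' samples x OTUs abundance matrix with unique sample and OTU identifiers.
#' Values are either raw counts or per-sample relative abundances
#' (`is_relative = TRUE`, each row summing to 1).
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns, with
#'   row and column names.
#' @param is_relative logical; `TRUE` if rows are relative abundances.
#' @return An object of class `community_table`: the validated matrix with
#'   attribute `is_relative`.
#' @examples
#' m <- matrix(c(5, 0, 0, 3, 1, 1), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("S", 1:3), c("OTU_1", "OTU_2")))
#' community_table(m)
#' @export
community_table <- function(counts, is_relative = FALSE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  validate_community_table(counts, is_relative)
  structure(counts, is_relative = is_relative, class = c("community_table", "matrix"))
}

validate_community_table <- function(counts, is_relative) {
  if (length(counts) == 0L) stop_value("community table is empty")
  sn <- rownames(counts)
  on <- colnames(counts)
  if (is.null(sn) || is.null(on)) {
    stop_value("community table must have sample (row) and OTU (column) names")
  }
  if (anyDuplicated(sn)) {
    stop_value("duplicate sample identifiers: %s",
               paste(unique(sn[duplicated(sn)]), collapse = ", "))
  }
  if (anyDuplicated(on)) {
    stop_value("duplicate OTU identifiers: %s",
               paste(unique(on[duplicated(on)]), collapse = ", "))
  }
  if (anyNA(counts) || !all(is.finite(counts))) {
    stop_value("community table contains missing or non-finite values")
  }
  if (any(counts < 0)) stop_value("community table contains negative abundances")
  if (is_relative) {
    rs <- rowSums(counts)
    bad <- abs(rs - 1) > 1e-9
    if (any(bad)) {
      stop_value("rows of a relative-abundance table must sum to 1; offending sample(s): %s",
                 paste(sn[bad], collapse = ", "))
    }
  }
  invisible(counts)
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d samples x %d OTUs (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "is_relative"))) "relative abundances" else "counts"))
  invisible(x)
}

is_relative <- function(table) isTRUE(attr(table, "is_relative"))

# Coerce a plain matrix to community_table, passing community_table through.
as_community_table <- function(x, is_relative = FALSE) {
  if (inherits(x, "community_table")) x else community_table(x, is_relative)
}

#' Convert counts to per-sample relative abundances
#'
#' Divides each sample row by its total. A table already flagged as relative
#' is returned unchanged.
#'
#' @param table a [community_table()].
#' @return A `community_table` with `is_relative = TRUE`.
#' @examples
#' m <- matrix(c(5, 0, 5, 2, 2, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("S1", "S2"), paste0("OTU_", 1:3)))
#' to_relative(community_table(m))
#' @export
to_relative <- function(table) {
  table <- as_community_table(table)
  if (is_relative(table)) return(table)
  rs <- rowSums(table)
  if (any(rs == 0)) {
    stop_value("sample(s) with zero total abundance: %s",
               paste(rownames(table)[rs == 0], collapse = ", "))
  }
  community_table(unclass(table) / rs, is_relative = TRUE)
}

# Drop the class/attribute wrapper; plain numeric matrix.
count_matrix <- function(table) {
  m <- unclass(table)
  attr(m, "is_relative") <- NULL
  m
}
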