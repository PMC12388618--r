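#' Read an OTU abundance table from TSV
#'
#' Reads a tab-separated abundance table with one header row and the first
#' column holding identifiers. Field conventions differ on orientation, so it
#' is an explicit argument and never guessed.
#'
#' @param path path to a TSV file.
#' @param orientation `"samples_as_rows"` (default) or `"otus_as_rows"`; with
#'   `"otus_as_rows"` the table is transposed after reading so the returned
#'   object is always samples x OTUs.
#' @param is_relative logical; whether the stored values are relative
#'   abundances rather than counts.
#' @return A [community_table()].
#' @export
read_community_table <- function(path,
                                 orientation = c("samples_as_rows", "otus_as_rows"),
                                 is_relative = FALSE) {
  orientation <- match.arg(orientation)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop_value("empty or id-only table: %s", path)
  ids <- as.character(raw[[1L]])
  hdr <- colnames(raw)[-1L]
  if (anyDuplicated(hdr)) {
    stop_value("duplicate column identifiers in %s: %s", path,
               paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop_value("duplicate row identifiers in %s: %s", path,
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop_value("non-numeric abundance values in %s", path)
  rownames(m) <- ids
  if (orientation == "otus_as_rows") m <- t(m)
  community_table(m, is_relative = is_relative)
}

#' Write a community table to TSV
#'
#' Inverse of [read_community_table()] with `orientation = "samples_as_rows"`;
#' integer count tables round-trip bit-identically.
#'
#' @param table a [community_table()].
#' @param path output path.
#' @param id_column name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(table, path, id_column = "sample_id") {
  table <- as_community_table(table)
  df <- data.frame(rownames(table), count_matrix(table), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' @param path TSV with mandatory columns `sample_id`, `site_id`, `salinity`
#'   (soil electrical conductivity, mS/cm); any further numeric columns are
#'   kept as environmental covariates.
#' @return A data.frame with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  validate_sample_metadata(df)
}

validate_sample_metadata <- function(df) {
  need <- c("sample_id", "site_id", "salinity")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop_value("metadata missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) {
    stop_value("duplicate sample_id in metadata: %s",
               paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  if (anyNA(df$salinity) || !is.numeric(df$salinity) || any(!is.finite(df$salinity)) ||
      any(df$salinity < 0)) {
    stop_value("salinity must be non-negative and finite for every sample")
  }
  df
}

# Check that metadata covers every sample of a table, and return metadata
# reordered to the table's samples.
align_metadata <- function(table, meta) {
  meta <- validate_sample_metadata(meta)
  miss <- setdiff(rownames(table), meta$sample_id)
  if (length(miss)) {
    stop_value("metadata missing for sample(s): %s", paste(miss, collapse = ", "))
  }
  meta[match(rownames(table), meta$sample_id), , drop = FALSE]
}

#' Patristic distances from a Newick phylogeny
#'
#' Reads a Newick tree ([ape::read.tree()]) and returns the symmetric
#' tip-to-tip patristic distance matrix over the requested OTUs, the substrate
#' of the beta nearest taxon index. Ultrametricity is not required; branch
#' lengths are used as stored.
#'
#' @param path path to a Newick file, or an object of class `phylo`.
#' @param otu_ids OTU identifiers the matrix must cover; defaults to all tips.
#' @return Square symmetric numeric matrix over `otu_ids` with zero diagonal.
#' @export
read_phylogeny <- function(path, otu_ids = NULL) {
  tree <- if (inherits(path, "phylo")) path else ape::read.tree(path)
  if (is.null(tree)) stop_value("could not parse Newick tree: %s", path)
  if (is.null(tree$edge.length)) stop_value("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop_value("tree has negative branch lengths")
  otu_ids <- otu_ids %||% tree$tip.label
  miss <- setdiff(otu_ids, tree$tip.label)
  if (length(miss)) {
    stop_value("tree is missing tip(s): %s", paste(miss, collapse = ", "))
  }
  d <- ape::cophenetic.phylo(tree)[otu_ids, otu_ids, drop = FALSE]
  validate_distance_matrix(d)
  d
}

validate_distance_matrix <- function(d, tol = 1e-12) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop_value("distance matrix must be square")
  if (anyNA(d)) stop_value("distance matrix contains NA")
  if (any(abs(d - t(d)) > tol)) stop_value("distance matrix is not symmetric")
  if (any(abs(diag(d)) > tol)) stop_value("distance matrix diagonal is not zero")
  if (any(d < 0)) stop_value("distance matrix has negative entries")
  invisible(d)
}

#' Define salinity levels
#'
#' Bin edges define left-closed, right-open intervals (the final interval is
#' closed on the right), so every salinity in range maps to exactly one level.
#' The defaults give the five levels 0-1, 1-2, 2-4, 4-7 and 7-11 mS/cm.
#'
#' @param bin_edges strictly increasing numeric vector of interval edges
#'   (mS/cm).
#' @param bin_labels optional labels, one per interval; defaults to
#'   `"lo-hi"` strings.
#' @return A list of class `salinity_binning`.
#' @export
salinity_binning <- function(bin_edges = c(0, 1, 2, 4, 7, 11), bin_labels = NULL) {
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0)) {
    stop_value("bin_edges must be strictly increasing with at least two values")
  }
  n <- length(bin_edges) - 1L
  labels <- bin_labels %||% paste0(bin_edges[-length(bin_edges)], "-", bin_edges[-1L])
  if (length(labels) != n || anyDuplicated(labels)) {
    stop_value("need %d distinct bin labels", n)
  }
  structure(list(bin_edges = as.numeric(bin_edges), bin_labels = as.character(labels)),
            class = "salinity_binning")
}

#' Assign samples to salinity levels
#'
#' @param meta metadata data.frame with `sample_id` and `salinity` columns.
#' @param binning a [salinity_binning()].
#' @return Named character vector (factor levels in bin order), sample_id ->
#'   bin label.
#' @examples
#' meta <- data.frame(sample_id = c("a", "b"), site_id = "s1",
#'                    salinity = c(1.5, 7))
#' assign_salinity_levels(meta, salinity_binning())
#' @export
assign_salinity_levels <- function(meta, binning = salinity_binning()) {
  meta <- validate_sample_metadata(meta)
  stopifnot(inherits(binning, "salinity_binning"))
  edges <- binning$bin_edges
  out <- meta$salinity < edges[1L] | meta$salinity > edges[length(edges)]
  if (any(out)) {
    stop_value("salinity outside binning range [%g, %g] for sample(s): %s",
               edges[1L], edges[length(edges)],
               paste(meta$sample_id[out], collapse = ", "))
  }
  idx <- findInterval(meta$salinity, edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  lv <- factor(binning$bin_labels[idx], levels = binning$bin_labels)
  setNames(as.character(lv), meta$sample_id)
}

#' Read a taxonomy table
#'
#' @param path TSV with columns `otu_id`, `genus`, `family`, `order`;
#'   unassigned ranks may carry any sentinel label (e.g. "unclassified").
#' @return data.frame keyed by `otu_id`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  need <- c("otu_id", "genus", "family", "order")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop_value("taxonomy missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$otu_id)) {
    stop_value("duplicate otu_id in taxonomy: %s",
               paste(unique(df$otu_id[duplicated(df$otu_id)]), collapse = ", "))
  }
  df
}
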