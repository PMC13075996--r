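#' Validate an ASV count matrix
#'
#' A count matrix is a plain integer matrix with ASV (feature) identifiers
#' as row names and sample identifiers as column names. `count_matrix()`
#' checks the container invariants — non-negative integral counts, unique
#' non-empty identifiers, dimensions matching the identifier sets — and
#' returns the matrix in integer storage.
#'
#' @param counts numeric or integer matrix, features as rows, samples as
#'   columns, with complete `dimnames`.
#' @return the validated matrix with integer storage mode.
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) fail("counts must be a matrix")
  fid <- rownames(counts)
  sid <- colnames(counts)
  if (is.null(fid) || is.null(sid)) fail("counts must have row and column names")
  if (any(fid == "") || any(sid == "")) fail("empty feature or sample identifier")
  if (anyDuplicated(fid)) {
    fail("duplicated feature id(s): %s",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    fail("duplicated sample id(s): %s",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  bad <- which(!(is_wholenumber(counts) & counts >= 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    fail("non-integer or negative count at feature '%s', sample '%s'",
         fid[bad[1, 1]], sid[bad[1, 2]])
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Read a tab-delimited ASV count table
#'
#' Reads a feature-by-sample count table. The canonical on-disk layout has
#' features as rows (first column = feature id, header = sample ids); a
#' transposed file can be read with `features_as_rows = FALSE`. A leading
#' `# Constructed from biom file` comment line (BIOM TSV export) is
#' tolerated and skipped.
#'
#' @param path file path.
#' @param features_as_rows logical; `FALSE` reads a samples-as-rows file.
#' @return validated count matrix (see [count_matrix()]).
#' @export
read_count_table <- function(path, features_as_rows = TRUE) {
  if (!file.exists(path)) fail("file not found: %s", path)
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#") && grepl("biom", first, ignore.case = TRUE)) 1L else 0L
  df <- read.delim(path, sep = "\t", header = TRUE, skip = skip,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) fail("count table needs an id column plus data columns")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    nonnum <- colnames(m)[!vapply(seq_len(ncol(m)), function(j)
      is.numeric(df[[j + 1]]), logical(1))][1]
    fail("non-numeric values in column '%s'", nonnum)
  }
  rownames(m) <- ids
  if (!features_as_rows) m <- t(m)
  count_matrix(m)
}

#' Write an ASV count table
#'
#' Features-as-rows tab-delimited output; round-trips exactly through
#' [read_count_table()].
#'
#' @param counts count matrix.
#' @param path output file path.
#' @param id_column name for the identifier column header.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, id_column = "feature_id") {
  counts <- count_matrix(counts)
  df <- data.frame(id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# rank prefixes of a Greengenes-style lineage string
.rank_prefixes <- c(domain = "d__", phylum = "p__", class = "c__",
                    order = "o__", family = "f__", genus = "g__")

#' Parse Greengenes-style lineage strings
#'
#' Splits semicolon-delimited lineages with `d__`/`p__`/`c__`/`o__`/`f__`/
#' `g__` prefixed ranks. Empty or absent ranks become `NA`.
#'
#' @param lineage character vector of lineage strings.
#' @return data.frame with one column per rank (domain...genus).
#' @export
parse_lineage <- function(lineage) {
  out <- matrix(NA_character_, nrow = length(lineage),
                ncol = length(.rank_prefixes),
                dimnames = list(NULL, names(.rank_prefixes)))
  for (i in seq_along(lineage)) {
    if (is.na(lineage[i])) next
    parts <- trimws(strsplit(lineage[i], ";", fixed = TRUE)[[1]])
    for (r in seq_along(.rank_prefixes)) {
      pref <- .rank_prefixes[r]
      hit <- parts[startsWith(parts, pref)]
      if (length(hit) >= 1) {
        val <- sub(pref, "", hit[1], fixed = TRUE)
        if (nzchar(val)) out[i, r] <- val
      }
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read a taxonomy table
#'
#' Two-column tab-delimited file: feature id, lineage string. Ranks are
#' parsed with [parse_lineage()]; missing ranks are `NA` in memory and the
#' empty string on disk.
#'
#' @param path file path.
#' @return data.frame with columns `feature_id`, `lineage`,
#'   `domain`..`genus`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) fail("taxonomy file needs feature id and lineage columns")
  tax <- data.frame(feature_id = as.character(df[[1]]),
                    lineage = as.character(df[[2]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tax$feature_id)) {
    fail("duplicated feature id(s) in taxonomy: %s",
         paste(unique(tax$feature_id[duplicated(tax$feature_id)]), collapse = ", "))
  }
  cbind(tax, parse_lineage(tax$lineage))
}

#' Write a taxonomy table
#' @param taxonomy data.frame as returned by [read_taxonomy()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write.table(taxonomy[, c("feature_id", "lineage")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Delimited file (tab or comma, auto-detected) with header containing at
#' least `sample_id`, `EFF`, `CH4Y`, `ACET_PROP`; extra columns (e.g. a
#' sampling-week label) are carried through.
#'
#' @param path file path.
#' @return data.frame, one row per sample.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "EFF", "CH4Y", "ACET_PROP")
  miss <- setdiff(need, names(df))
  if (length(miss)) fail("phenotype table missing column(s): %s",
                         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) fail("duplicated sample id in phenotypes")
  vals <- as.matrix(df[, c("EFF", "CH4Y", "ACET_PROP")])
  if (!all(is.finite(vals))) fail("non-finite phenotype value")
  if (any(df$CH4Y <= 0)) fail("CH4Y must be positive")
  if (any(df$ACET_PROP <= 0)) fail("ACET_PROP must be positive")
  df
}

#' Write a phenotype table
#' @param phenotypes data.frame with `sample_id`, `EFF`, `CH4Y`,
#'   `ACET_PROP` (extra columns kept).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network edge list
#'
#' Tab-delimited columns `node_a`, `node_b`, `correlation` (6 decimals),
#' `edge_type`, ordered by (edge_type, node_a, node_b) so output is
#' deterministic.
#'
#' @param edges data.frame with those four columns, or a
#'   `coassoc_network` (its full edge set is written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  if (inherits(edges, "coassoc_network")) edges <- edges$edges
  need <- c("node_a", "node_b", "correlation", "edge_type")
  miss <- setdiff(need, names(edges))
  if (length(miss)) fail("edge list missing column(s): %s", paste(miss, collapse = ", "))
  edges <- validate_edges(edges)
  ord <- order(edges$edge_type, edges$node_a, edges$node_b)
  edges <- edges[ord, need, drop = FALSE]
  out <- edges
  out$correlation <- sprintf("%.6f", edges$correlation)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network edge list written by [write_edge_list()]
#' @param path file path.
#' @return data.frame with columns `node_a`, `node_b`, `correlation`,
#'   `edge_type`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric", "character"))
  validate_edges(df)
}

# EdgeList invariants: no self loops, no duplicate unordered pairs,
# correlations nonzero in [-1, 1], known edge types
validate_edges <- function(edges) {
  if (nrow(edges) == 0) return(edges)
  if (any(edges$node_a == edges$node_b)) fail("self-loop edge")
  key <- apply(cbind(pmin(edges$node_a, edges$node_b),
                     pmax(edges$node_a, edges$node_b)), 1, paste, collapse = "\r")
  if (anyDuplicated(key)) fail("duplicate unordered edge pair")
  if (any(!is.finite(edges$correlation)) || any(abs(edges$correlation) > 1) ||
      any(edges$correlation == 0)) {
    fail("edge correlations must be nonzero and within [-1, 1]")
  }
  if (!all(edges$edge_type %in% c("asv-asv", "asv-phenotype", "phenotype-phenotype"))) {
    fail("unknown edge_type")
  }
  edges
}
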