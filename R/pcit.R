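#' Pearson correlation matrix over ASVs and phenotypes
#'
#' Builds the node-by-node correlation matrix used for network inference:
#' phenotype columns are treated exactly like ASV rows. Complete cases
#' only — samples with any missing value are dropped before correlation,
#' so all entries come from one consistent sample set.
#'
#' @param abundances numeric matrix (features x samples), e.g. CSS-log2
#'   abundances.
#' @param phenotypes optional data.frame with `sample_id` plus numeric
#'   phenotype columns; sample ids must match the abundance columns.
#' @param phenotype_names which phenotype columns to include (default all
#'   numeric columns except `sample_id` and `week`).
#' @return symmetric correlation matrix with unit diagonal, ASV then
#'   phenotype nodes; attribute `phenotype_nodes` lists the phenotype
#'   node names.
#' @export
correlation_matrix <- function(abundances, phenotypes = NULL,
                               phenotype_names = NULL) {
  m <- t(as.matrix(abundances))  # samples x features
  if (!is.null(phenotypes)) {
    if (is.null(phenotype_names)) {
      phenotype_names <- setdiff(names(phenotypes)[vapply(phenotypes, is.numeric,
                                                          logical(1))], "week")
    }
    idx <- match(rownames(m), phenotypes$sample_id)
    if (anyNA(idx)) fail("phenotype table missing sample(s): %s",
                         paste(rownames(m)[is.na(idx)], collapse = ", "))
    ph <- as.matrix(phenotypes[idx, phenotype_names, drop = FALSE])
    rownames(ph) <- rownames(m)
    m <- cbind(m, ph)
  }
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 4) fail("fewer than 4 complete-case samples")
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) fail("zero-variance node(s): %s",
                        paste(colnames(m)[v == 0], collapse = ", "))
  r <- stats::cor(m)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(r, phenotype_nodes = phenotype_names)
}

#' PCIT co-association network
#'
#' Applies the partial-correlation-and-information-theory filter to a
#' correlation matrix: every unordered trio of nodes is examined, the
#' three first-order partial correlations give a data-driven tolerance
#' (the mean ratio of partial to direct correlation), and an edge is
#' discarded when, in some trio, its correlation magnitude falls below
#' the tolerance times both correlations with the third node — i.e. when
#' the association is explainable by that third variable. Retained edges
#' are the direct, conditionally independent associations. The result is
#' independent of node order and trio enumeration order.
#'
#' Trios containing a degenerate correlation (|r| below the guard or
#' |r| = 1, which makes a partial correlation undefined) are skipped and
#' counted; they produce no flags.
#'
#' @param corr symmetric correlation matrix with unit diagonal (see
#'   [correlation_matrix()]), at least 3 nodes, no missing values.
#' @param guard numeric guard for degenerate denominators (default
#'   1e-12).
#' @return object of class `coassoc_network`: list with `node_ids`,
#'   `edges` (data.frame `node_a`, `node_b`, `correlation`, `edge_type`),
#'   `n_skipped_trios`, and `phenotype_nodes`.
#' @export
pcit <- function(corr, guard = 1e-12) {
  corr <- as.matrix(corr)
  n <- nrow(corr)
  if (n < 3) fail("PCIT needs at least 3 nodes")
  if (anyNA(corr)) fail("NaN/NA correlation")
  if (max(abs(corr - t(corr))) > 1e-12) fail("correlation matrix not symmetric")
  if (any(abs(diag(corr) - 1) > 1e-12)) fail("diagonal must be 1")
  if (max(abs(corr)) > 1 + 1e-12) fail("|r| > 1")
  ids <- rownames(corr)
  if (is.null(ids)) ids <- paste0("node", seq_len(n))
  scan <- .pcit_scan(corr, guard)
  keep <- !scan$flagged & corr != 0 & upper.tri(corr)
  idx <- which(keep, arr.ind = TRUE)
  pheno <- attr(corr, "phenotype_nodes")
  if (is.null(pheno)) pheno <- character(0)
  edge_type_of <- function(a, b) {
    na <- a %in% pheno
    nb <- b %in% pheno
    ifelse(na & nb, "phenotype-phenotype",
           ifelse(na | nb, "asv-phenotype", "asv-asv"))
  }
  edges <- data.frame(node_a = ids[idx[, 1]], node_b = ids[idx[, 2]],
                      correlation = corr[keep],
                      stringsAsFactors = FALSE)
  edges$edge_type <- if (nrow(edges)) edge_type_of(edges$node_a, edges$node_b) else character(0)
  structure(list(node_ids = ids, edges = edges,
                 n_skipped_trios = scan$skipped,
                 phenotype_nodes = pheno),
            class = "coassoc_network")
}

#' @export
print.coassoc_network <- function(x, ...) {
  cat(sprintf("PCIT co-association network: %d nodes, %d retained edges",
              length(x$node_ids), nrow(x$edges)))
  if (length(x$phenotype_nodes)) {
    cat(sprintf(" (%d phenotype nodes)", length(x$phenotype_nodes)))
  }
  cat(sprintf("\nskipped degenerate trios: %s\n",
              format(x$n_skipped_trios, big.mark = ",")))
  invisible(x)
}

#' ASV-phenotype edges of a co-association network
#'
#' Partitions the edges incident to each phenotype node, excluding
#' ASV-ASV and phenotype-phenotype edges. ASVs directly connected to a
#' phenotype are its candidate predictors.
#'
#' @param network a `coassoc_network` from [pcit()].
#' @param phenotype_names phenotype node names (default: the network's
#'   phenotype nodes).
#' @return named list, one data.frame per phenotype with columns
#'   `asv_id`, `correlation`, `sign`.
#' @export
phenotype_edges <- function(network, phenotype_names = NULL) {
  if (is.null(phenotype_names)) phenotype_names <- network$phenotype_nodes
  unknown <- setdiff(phenotype_names, network$node_ids)
  if (length(unknown)) fail("unknown phenotype node(s): %s",
                            paste(unknown, collapse = ", "))
  e <- network$edges
  out <- list()
  for (ph in phenotype_names) {
    hit <- (e$node_a == ph | e$node_b == ph) & e$edge_type == "asv-phenotype"
    sub <- e[hit, , drop = FALSE]
    asv <- ifelse(sub$node_a == ph, sub$node_b, sub$node_a)
    df <- data.frame(asv_id = asv, correlation = sub$correlation,
                     sign = sign(sub$correlation), stringsAsFactors = FALSE)
    out[[ph]] <- df[order(df$asv_id), , drop = FALSE]
    rownames(out[[ph]]) <- NULL
  }
  out
}
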