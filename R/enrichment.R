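#' Family-level hypergeometric enrichment
#'
#' Tests whether the ASVs selected by the network (e.g. those directly
#' connected to a phenotype) over-represent particular taxonomic families
#' relative to the network background. For a family with K members among
#' the N background ASVs, of which x appear in the selection of size n,
#' the upper-tail hypergeometric probability P(X >= x) is computed and
#' reported as a score of -log10(p); higher scores mean stronger
#' enrichment. ASVs without a family assignment are excluded from both
#' the background and the selection, so classification failure cannot
#' manufacture enrichment. Only families with x >= `min_count` are
#' reported.
#'
#' @param selected_ids ASV ids of the selection; must be a subset of
#'   `background_ids`.
#' @param background_ids ASV ids of the background (e.g. all network
#'   ASVs).
#' @param taxonomy taxonomy data.frame with `feature_id` and `family`.
#' @param min_count minimum selected count per reported family
#'   (default 2).
#' @return data.frame with columns `family`, `x`, `K`, `n`, `N`,
#'   `p_upper`, `score`, `p_adj_bh` (Benjamini-Hochberg over the reported
#'   families, provided as an optional extra), sorted by decreasing score
#'   with ties broken by family name.
#' @export
family_enrichment <- function(selected_ids, background_ids, taxonomy,
                              min_count = 2) {
  extra <- setdiff(selected_ids, background_ids)
  if (length(extra)) fail("selected ids not in background: %s",
                          paste(head(extra, 5), collapse = ", "))
  fam <- taxonomy$family[match(background_ids, taxonomy$feature_id)]
  names(fam) <- background_ids
  bg <- fam[!is.na(fam)]
  if (length(bg) == 0) fail("no background ASV has a family assignment")
  sel <- fam[selected_ids]
  sel <- sel[!is.na(sel)]
  N <- length(bg)
  n <- length(sel)
  K_tab <- table(bg)
  x_tab <- table(factor(sel, levels = names(K_tab)))
  res <- data.frame(family = names(K_tab),
                    x = as.integer(x_tab),
                    K = as.integer(K_tab),
                    n = n, N = N, stringsAsFactors = FALSE)
  res <- res[res$x >= min_count, , drop = FALSE]
  if (nrow(res) == 0) {
    res$p_upper <- numeric(0); res$score <- numeric(0)
    res$p_adj_bh <- numeric(0)
    return(res)
  }
  res$p_upper <- stats::phyper(res$x - 1, res$K, res$N - res$K, res$n,
                               lower.tail = FALSE)
  res$score <- -log10(res$p_upper)
  res$p_adj_bh <- stats::p.adjust(res$p_upper, method = "BH")
  res <- res[order(-res$score, res$family), , drop = FALSE]
  rownames(res) <- NULL
  res
}
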