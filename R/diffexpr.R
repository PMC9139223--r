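# Fold-change ranking of genes in a gated subset of a sample against the
# same subset of a reference sample.

#' Counts-per-10k normalization
#'
#' Scales every cell's counts to a library size of `scale` (default 1e4,
#' the counts-per-10k convention for targeted single-cell panels). Cells
#' with zero total counts are dropped with a message.
#'
#' @param expr cells-by-genes count matrix.
#' @param scale target library size per cell.
#' @return a normalized matrix of the same orientation.
#' @export
normalize_cpm <- function(expr, scale = 1e4) {
  totals <- Matrix::rowSums(expr)
  zero <- totals == 0
  if (all(zero)) stop("all cells have zero total counts")
  if (any(zero)) {
    message("dropped ", sum(zero), " cell(s) with zero total counts")
    expr <- expr[!zero, , drop = FALSE]
    totals <- totals[!zero]
  }
  Matrix::Diagonal(x = scale / totals) %*% expr
}

#' Rank genes by log2 fold change between gated subsets
#'
#' Computes, for every gene shared by the two matrices,
#' `log2((mean_sample + pseudocount) / (mean_ref + pseudocount))` of the
#' per-cell normalized expression over the gated cells of the sample and
#' of the reference, and returns the full ranking by decreasing fold
#' change. No significance testing is attached: the output is a ranking
#' statistic for top-10 up/down reports.
#'
#' @param expr_sample,expr_ref cells-by-genes count matrices.
#' @param cells_sample,cells_ref gated cell ids (default: all cells).
#' @param pseudocount positive stabilizer added to both means (default 1).
#' @param scale normalization library size (see [normalize_cpm()]).
#' @return a `de_ranking` data frame: `gene_id`, `log2_fc`, `mean_sample`,
#'   `mean_ref`, ordered by `log2_fc` descending.
#' @export
rank_fold_changes <- function(expr_sample, expr_ref,
                              cells_sample = rownames(expr_sample),
                              cells_ref = rownames(expr_ref),
                              pseudocount = 1, scale = 1e4) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  genes <- intersect(colnames(expr_sample), colnames(expr_ref))
  if (length(genes) == 0L) stop("sample and reference share no genes")
  n_drop <- max(ncol(expr_sample), ncol(expr_ref)) - length(genes)
  if (n_drop > 0) message("restricted to ", length(genes), " shared gene(s)")
  cells_sample <- intersect(cells_sample, rownames(expr_sample))
  cells_ref <- intersect(cells_ref, rownames(expr_ref))
  if (length(cells_sample) == 0L || length(cells_ref) == 0L) {
    stop("gated subset is empty in sample or reference")
  }
  ms <- Matrix::colMeans(normalize_cpm(expr_sample[cells_sample, genes,
                                                   drop = FALSE],
                                       scale = scale))
  mr <- Matrix::colMeans(normalize_cpm(expr_ref[cells_ref, genes,
                                                drop = FALSE],
                                       scale = scale))
  # written as a difference of logs so that swapping sample and reference
  # negates every value bitwise
  lfc <- log2(ms + pseudocount) - log2(mr + pseudocount)
  out <- data.frame(gene_id = genes, log2_fc = unname(lfc),
                    mean_sample = unname(ms), mean_ref = unname(mr),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$log2_fc, out$gene_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("de_ranking", "data.frame"))
}

#' Top up- and down-regulated genes of a ranking
#'
#' @param ranking a `de_ranking` from [rank_fold_changes()].
#' @param n number of genes per direction (default 10).
#' @return list with `up` (largest fold changes, descending) and `down`
#'   (smallest, ascending).
#' @export
top_de <- function(ranking, n = 10) {
  list(up = utils::head(ranking, n),
       down = utils::head(ranking[order(ranking$log2_fc, ranking$gene_id,
                                        method = "radix"), , drop = FALSE],
                          n))
}
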