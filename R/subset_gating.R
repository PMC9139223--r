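# Marker-UMI gating of cell subsets (CD8+, FOXP3+) and restriction of
# repertoire statistics to gated cells.

# The capture panel's CD8 feature may be named CD8 or CD8A depending on the
# panel release; resolve the common aliases.
MARKER_ALIASES <- c(CD8 = "CD8A")

resolve_marker <- function(marker, gene_ids) {
  if (marker %in% gene_ids) return(marker)
  alias <- unname(MARKER_ALIASES[marker])
  if (!is.na(alias) && alias %in% gene_ids) {
    message("marker '", marker, "' resolved to panel gene '", alias, "'")
    return(alias)
  }
  near <- unique(c(agrep(marker, gene_ids, value = TRUE, ignore.case = TRUE,
                         max.distance = 0.25),
                   grep(paste0("^", marker), gene_ids, value = TRUE,
                        ignore.case = TRUE)))
  stop("marker '", marker, "' not found in the expression matrix",
       if (length(near)) paste0("; near matches: ",
                                paste(utils::head(near, 5), collapse = ", ")))
}

#' Gate cells on a marker UMI threshold
#'
#' A cell belongs to the marker-positive subset when it carries at least
#' `min_umi` raw UMI counts of the marker gene (default 1, i.e. cells
#' expressing one or more copies). Gating uses raw counts, never
#' normalized values.
#'
#' @param expr cells-by-genes count matrix with dimnames (see
#'   [read_expression()]).
#' @param marker marker gene id; the alias `"CD8"` resolves to `"CD8A"`
#'   when the panel uses the latter.
#' @param min_umi positive integer threshold.
#' @return character vector of gated cell ids.
#' @export
gate_cells <- function(expr, marker, min_umi = 1) {
  if (length(min_umi) != 1L || !is.finite(min_umi) || min_umi < 1 ||
      min_umi != round(min_umi)) {
    stop("min_umi must be a positive integer")
  }
  marker <- resolve_marker(marker, colnames(expr))
  rownames(expr)[as.numeric(expr[, marker]) >= min_umi]
}

#' Restrict chain records to a cell set
#'
#' @param records chain-record data frame.
#' @param cells character vector of cell ids.
#' @return the records whose `cell_id` is in `cells`, order preserved.
#' @export
subset_records <- function(records, cells) {
  records[records$cell_id %in% cells, , drop = FALSE]
}

#' Diversity of a gated subset
#'
#' Shannon index of the chosen repertoire entity restricted to a gated
#' cell set, e.g. the TRA CDR3 diversity of FOXP3+ cells. Bounded by
#' `log` of the number of distinct entities present in the subset.
#'
#' @param records chain-record data frame.
#' @param cells gated cell ids (non-empty after intersection with the
#'   records).
#' @inheritParams repertoire_diversity
#' @return H' of the subset.
#' @export
subset_diversity <- function(records, cells, entity = "cdr3_aa",
                             locus = "TRA") {
  sub <- subset_records(records, cells)
  if (nrow(sub) == 0L) stop("gated subset contains no chain records")
  repertoire_diversity(sub, entity, locus)
}
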