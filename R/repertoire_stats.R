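# Repertoire statistics: segment usage vectors, V-J pairing matrices,
# Shannon diversity, and paired clonotype assembly/ranking.

new_frequency_table <- function(label, count, weight_basis,
                                locus = NA_character_,
                                segment_type = NA_character_) {
  total <- sum(count)
  df <- data.frame(label = label, count = count,
                   percent = if (total > 0) 100 * count / total
                             else rep(NA_real_, length(count)),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("frequency_table", "data.frame"),
            weight_basis = weight_basis, locus = locus,
            segment_type = segment_type)
}

resolve_weights <- function(records, weight_basis) {
  switch(weight_basis,
         molecules = records$molecule_count,
         reads = records$read_count,
         cells = rep(1L, nrow(records)),
         stop("unknown weight_basis: ", weight_basis))
}

# Shared filtering for usage/pairing: restrict to locus, normalize calls,
# attach functionality from the catalog.
prepare_locus_records <- function(records, locus, catalog) {
  locus <- match.arg(locus, c("TRA", "TRB"))
  rec <- records[records$locus == locus, , drop = FALSE]
  if (nrow(rec) == 0L) return(rec)
  rec$v_call <- normalize_segment_name(rec$v_call, locus)
  rec$j_call <- normalize_segment_name(rec$j_call, locus)
  rec
}

#' Segment usage frequencies
#'
#' Percentage usage of V (or J) germline segments at one locus, after
#' excluding segments outside the requested functionality classes from
#' both numerator and denominator. Weighting is by UMI-collapsed molecule
#' counts by default; read counts and cell counts (one per distinct
#' cell-segment pair) are also supported. Segments whose weighted count
#' falls below `min_count` are dropped from the label set; with
#' `min_count = 0` every kept catalog segment appears, zero counts
#' included.
#'
#' @param records chain-record data frame (see [read_rearrangements()]).
#' @param locus `"TRA"` or `"TRB"`.
#' @param segment_type `"V"` or `"J"`.
#' @param catalog a `segment_catalog`; observed segments missing from it
#'   are kept as functional with a warning.
#' @param keep functionality classes retained (default `"functional"`).
#' @param weight_basis `"molecules"`, `"reads"` or `"cells"`.
#' @param min_count low-expression cutoff on the weighted count
#'   (default 1: never-observed segments are dropped from the labels).
#' @return a `frequency_table` data frame: `label`, `count`, `percent`.
#' @export
segment_usage <- function(records, locus, segment_type,
                          catalog = default_catalog(),
                          keep = "functional",
                          weight_basis = c("molecules", "reads", "cells"),
                          min_count = 1) {
  weight_basis <- match.arg(weight_basis)
  segment_type <- match.arg(segment_type, c("V", "J"))
  rec <- prepare_locus_records(records, locus, catalog)
  kept_catalog <- filter_segments(catalog, keep)
  universe <- catalog_segments(kept_catalog, locus, segment_type)
  if (nrow(rec) == 0L) {
    return(new_frequency_table(character(), numeric(), weight_basis,
                               locus, segment_type))
  }
  calls <- if (segment_type == "V") rec$v_call else rec$j_call
  fun <- lookup_functionality(calls, catalog)
  sel <- fun %in% keep
  rec <- rec[sel, , drop = FALSE]
  calls <- calls[sel]
  if (weight_basis == "cells") {
    dup <- duplicated(paste0(rec$cell_id, "\r", calls))
    rec <- rec[!dup, , drop = FALSE]
    calls <- calls[!dup]
  }
  w <- resolve_weights(rec, weight_basis)
  universe <- c(universe, setdiff(sort(unique(calls)), universe))
  count <- stats::setNames(numeric(length(universe)), universe)
  if (length(calls)) {
    obs <- tapply(w, calls, sum)
    count[names(obs)] <- obs
  }
  drop <- count < min_count
  new_frequency_table(universe[!drop], unname(count[!drop]), weight_basis,
                      locus, segment_type)
}

#' V-J pairing frequency matrix
#'
#' Percentage frequency of every V-J recombination at one locus over the
#' filtered segment catalog. Row labels are V segments, columns are J
#' segments; entries sum to 100. By default the matrix spans the full
#' filtered catalog (zero rows/columns included), so its number of cells
#' equals [possible_recombinants()] of the filtered segment counts.
#'
#' @inheritParams segment_usage
#' @param min_count drop V (J) labels whose total weighted count is below
#'   this (default 0: full catalog shape).
#' @return a `pairing_matrix`: list with `percent` and `count` matrices
#'   and `v_labels`, `j_labels`.
#' @export
vj_pairing <- function(records, locus, catalog = default_catalog(),
                       keep = "functional",
                       weight_basis = c("molecules", "reads", "cells"),
                       min_count = 0) {
  weight_basis <- match.arg(weight_basis)
  rec <- prepare_locus_records(records, locus, catalog)
  kept <- filter_segments(catalog, keep)
  v_labels <- catalog_segments(kept, locus, "V")
  j_labels <- catalog_segments(kept, locus, "J")
  if (nrow(rec) > 0L) {
    fun_v <- lookup_functionality(rec$v_call, catalog)
    fun_j <- lookup_functionality(rec$j_call, catalog)
    rec <- rec[fun_v %in% keep & fun_j %in% keep, , drop = FALSE]
    if (weight_basis == "cells") {
      rec <- rec[!duplicated(paste0(rec$cell_id, "\r", rec$v_call, "\r",
                                    rec$j_call)), , drop = FALSE]
    }
    v_labels <- c(v_labels, setdiff(sort(unique(rec$v_call)), v_labels))
    j_labels <- c(j_labels, setdiff(sort(unique(rec$j_call)), j_labels))
  }
  count <- matrix(0, length(v_labels), length(j_labels),
                  dimnames = list(v_labels, j_labels))
  if (nrow(rec) > 0L) {
    w <- resolve_weights(rec, weight_basis)
    obs <- tapply(w, list(factor(rec$v_call, v_labels),
                          factor(rec$j_call, j_labels)), sum)
    obs[is.na(obs)] <- 0
    count <- obs
  }
  if (min_count > 0) {
    count <- count[rowSums(count) >= min_count,
                   colSums(count) >= min_count, drop = FALSE]
  }
  total <- sum(count)
  structure(list(count = count,
                 percent = if (total > 0) 100 * count / total else count,
                 v_labels = rownames(count), j_labels = colnames(count),
                 weight_basis = weight_basis, locus = locus),
            class = "pairing_matrix")
}

#' @export
print.pairing_matrix <- function(x, ...) {
  cat("V-J pairing matrix (", x$locus, "): ", length(x$v_labels), " V x ",
      length(x$j_labels), " J = ",
      length(x$v_labels) * length(x$j_labels), " recombinants\n", sep = "")
  invisible(x)
}

#' Shannon diversity index
#'
#' The Shannon index H' = -sum(p_i * log(p_i)) over the frequencies of
#' repertoire entities, with natural logarithm. Input may be counts or
#' proportions; it is normalized to sum to one and zero entries are
#' skipped, so the index is scale-invariant and bounded by `log(S)` where
#' `S` is the number of positive entries.
#'
#' @param x non-negative numeric vector with at least one positive entry.
#' @return H', a non-negative scalar.
#' @examples
#' shannon_index(rep(1, 4)) # log(4)
#' @export
shannon_index <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L || anyNA(x) || any(x < 0)) {
    stop("shannon_index requires non-negative, non-missing input")
  }
  total <- sum(x)
  if (total <= 0) stop("shannon_index requires at least one positive entry")
  p <- x[x > 0] / total
  -sum(p * log(p))
}

#' Assemble paired clonotypes per cell
#'
#' For every cell, the TRA chain and the TRB chain with the largest
#' molecule count are selected (ties broken by lexicographically smallest
#' `junction_aa`, then `v_call`). Cells lacking either locus are reported
#' as unpaired and excluded from the paired table. The clonotype identity
#' is the 6-tuple (TRAV, CDR3a, TRAJ, TRBV, CDR3b, TRBJ); frequencies are
#' percentages of all paired cells.
#'
#' @param records chain-record data frame.
#' @return a `clonotype_assembly` list: `cells` (one row per paired cell),
#'   `clonotypes` (aggregated, with `n_cells` and `frequency_percent`),
#'   `unpaired` (cell ids), `n_paired`.
#' @export
assemble_clonotypes <- function(records) {
  rec <- records[records$locus %in% c("TRA", "TRB"), , drop = FALSE]
  for (loc in c("TRA", "TRB")) {
    i <- rec$locus == loc
    if (any(i)) {
      rec$v_call[i] <- normalize_segment_name(rec$v_call[i], loc)
      rec$j_call[i] <- normalize_segment_name(rec$j_call[i], loc)
    }
  }
  ord <- order(rec$cell_id, rec$locus, -rec$molecule_count,
               rec$junction_aa, rec$v_call, method = "radix")
  rec <- rec[ord, , drop = FALSE]
  best <- rec[!duplicated(paste0(rec$cell_id, "\r", rec$locus)), ,
              drop = FALSE]
  tra <- best[best$locus == "TRA", c("cell_id", "v_call", "junction_aa",
                                     "j_call")]
  trb <- best[best$locus == "TRB", c("cell_id", "v_call", "junction_aa",
                                     "j_call")]
  names(tra) <- c("cell_id", "tra_v", "cdr3_a", "tra_j")
  names(trb) <- c("cell_id", "trb_v", "cdr3_b", "trb_j")
  cells <- merge(tra, trb, by = "cell_id", sort = TRUE)
  unpaired <- setdiff(unique(rec$cell_id), cells$cell_id)
  key_cols <- c("tra_v", "cdr3_a", "tra_j", "trb_v", "cdr3_b", "trb_j")
  n_paired <- nrow(cells)
  if (n_paired > 0L) {
    key <- do.call(paste, c(cells[key_cols], sep = "\r"))
    tab <- table(key)
    first <- cells[!duplicated(key), c("cell_id", key_cols), drop = FALSE]
    clon <- first[match(names(tab), do.call(paste, c(first[key_cols],
                                                     sep = "\r"))),
                  key_cols, drop = FALSE]
    clon$n_cells <- as.integer(tab)
    clon$frequency_percent <- 100 * clon$n_cells / n_paired
    ordc <- order(-clon$n_cells, clon$tra_v, clon$cdr3_a, clon$tra_j,
                  clon$trb_v, clon$cdr3_b, clon$trb_j, method = "radix")
    clon <- clon[ordc, , drop = FALSE]
    rownames(clon) <- NULL
  } else {
    clon <- data.frame(tra_v = character(), cdr3_a = character(),
                       tra_j = character(), trb_v = character(),
                       cdr3_b = character(), trb_j = character(),
                       n_cells = integer(), frequency_percent = numeric())
  }
  structure(list(cells = cells, clonotypes = clon, unpaired = unpaired,
                 n_paired = n_paired),
            class = "clonotype_assembly")
}

#' @export
print.clonotype_assembly <- function(x, ...) {
  cat("Paired clonotype assembly: ", x$n_paired, " paired cell(s), ",
      nrow(x$clonotypes), " clonotype(s), ", length(x$unpaired),
      " unpaired cell(s)\n", sep = "")
  invisible(x)
}

#' Top-n clonotype table
#'
#' Clonotypes ranked by cell count (ties by lexicographic 6-tuple), with
#' frequency over all paired cells. Frequencies are kept at full precision;
#' report writers round to one decimal.
#'
#' @param assembly a `clonotype_assembly` from [assemble_clonotypes()].
#' @param n number of clonotypes to return (clipped to the table size).
#' @return data frame with `clone_id`, `frequency_percent` and the six
#'   identity columns, frequencies non-increasing.
#' @export
top_clonotypes <- function(assembly, n = 10) {
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("n must be >= 1")
  clon <- assembly$clonotypes
  top <- utils::head(clon, n)
  if (nrow(top)) top <- cbind(clone_id = seq_len(nrow(top)), top)
  rownames(top) <- NULL
  top
}

# Counts per diversity entity. Chain-level entities are weighted by
# molecule counts; the paired clonotype entity by cells.
entity_counts <- function(records, entity = c("cdr3_aa", "vj_pair",
                                              "per_chain_cdr3", "clonotype"),
                          locus = "TRA") {
  entity <- match.arg(entity)
  if (entity == "clonotype") {
    asm <- assemble_clonotypes(records)
    return(stats::setNames(asm$clonotypes$n_cells,
                           do.call(paste, c(asm$clonotypes[1:6], sep = "|"))))
  }
  rec <- records[records$locus == match.arg(locus, c("TRA", "TRB")), ,
                 drop = FALSE]
  if (nrow(rec) == 0L) return(stats::setNames(numeric(), character()))
  key <- switch(entity,
                cdr3_aa = rec$junction_aa,
                vj_pair = paste(rec$v_call, rec$j_call, sep = "|"),
                per_chain_cdr3 = paste(rec$v_call, rec$junction_aa,
                                       rec$j_call, sep = "|"))
  tapply(rec$molecule_count, key, sum)
}

#' Repertoire diversity for a chosen entity
#'
#' Shannon index over the frequency distribution of a repertoire entity:
#' per-locus CDR3 amino-acid sequences (default), V-J pairs, per-chain
#' V/CDR3/J triples, or paired clonotypes.
#'
#' @param records chain-record data frame.
#' @param entity one of `"cdr3_aa"`, `"vj_pair"`, `"per_chain_cdr3"`,
#'   `"clonotype"`.
#' @param locus locus for chain-level entities (ignored for clonotypes).
#' @return H' for the entity distribution.
#' @export
repertoire_diversity <- function(records, entity = "cdr3_aa", locus = "TRA") {
  shannon_index(entity_counts(records, entity, locus))
}
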