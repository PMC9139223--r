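# AIRR Rearrangement I/O, expression matrix I/O, and the read -> molecule
# folding step of the upstream pipeline.

AIRR_REQUIRED <- c("cell_id", "locus", "v_call", "j_call", "junction_aa")

# general numeric compressed-sparse-column form, whatever specialised
# shape (pattern, symmetric, triangular) the Matrix parsers return
as_dgc <- function(m) {
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

chain_records <- function(cell_id, locus, v_call, j_call, junction_aa,
                          molecule_count = 1L, read_count = molecule_count) {
  df <- data.frame(cell_id = as.character(cell_id),
                   locus = as.character(locus),
                   v_call = as.character(v_call),
                   j_call = as.character(j_call),
                   junction_aa = as.character(junction_aa),
                   molecule_count = as.integer(molecule_count),
                   read_count = as.integer(read_count),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$molecule_count <= df$read_count))
  df
}

#' Read an AIRR Rearrangement table
#'
#' Reads a tab-separated AIRR Rearrangement file: one row per recovered
#' chain per cell, with at least `cell_id`, `locus`, `v_call`, `j_call`
#' and `junction_aa`. The optional `duplicate_count` column is taken as
#' the UMI-collapsed molecule count (default 1); `read_count` defaults to
#' the molecule count when absent. Rows whose locus is neither TRA nor TRB
#' (e.g. IG chains) are dropped with a message.
#'
#' @param path path to the TSV file. Lines starting with `#` are ignored.
#' @return a data frame of chain records with columns `cell_id`, `locus`,
#'   `v_call`, `j_call`, `junction_aa`, `molecule_count`, `read_count`.
#' @export
read_rearrangements <- function(path) {
  if (!file.exists(path)) stop("rearrangement file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character", comment.char = "#",
                          quote = "", check.names = FALSE)
  missing <- setdiff(AIRR_REQUIRED, names(df))
  if (length(missing)) {
    stop("rearrangement file lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  keep <- df$locus %in% c("TRA", "TRB")
  if (any(!keep)) {
    message("dropped ", sum(!keep), " row(s) with locus outside TRA/TRB")
    df <- df[keep, , drop = FALSE]
  }
  mol <- if ("duplicate_count" %in% names(df)) {
    n <- suppressWarnings(as.integer(df$duplicate_count))
    ifelse(is.na(n), 1L, n)
  } else {
    rep(1L, nrow(df))
  }
  rdc <- if ("read_count" %in% names(df)) {
    n <- suppressWarnings(as.integer(df$read_count))
    ifelse(is.na(n), mol, pmax(n, mol))
  } else {
    mol
  }
  chain_records(df$cell_id, df$locus, df$v_call, df$j_call, df$junction_aa,
                mol, rdc)
}

#' Write chain records as an AIRR Rearrangement table
#'
#' @param records a chain-record data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(records, path) {
  out <- data.frame(cell_id = records$cell_id, locus = records$locus,
                    v_call = records$v_call, j_call = records$j_call,
                    junction_aa = records$junction_aa,
                    duplicate_count = records$molecule_count,
                    read_count = records$read_count)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell-by-gene UMI count matrix
#'
#' Accepts either a MatrixMarket triplet file (`.mtx`, cells as rows) with
#' companion one-name-per-line cell and gene files, or a dense TSV with
#' cell ids in the first column and gene ids as header.
#'
#' @param matrix_path path to the `.mtx` or dense TSV file.
#' @param cells_path,genes_path companion name files (required for `.mtx`).
#' @return a sparse `dgCMatrix`, cells as rows, genes as columns.
#' @export
read_expression <- function(matrix_path, cells_path = NULL,
                            genes_path = NULL) {
  if (!file.exists(matrix_path)) {
    stop("expression matrix not found: ", matrix_path)
  }
  if (grepl("\\.mtx$", matrix_path)) {
    if (is.null(cells_path) || is.null(genes_path)) {
      stop("cells_path and genes_path are required with a MatrixMarket file")
    }
    m <- as_dgc(Matrix::readMM(matrix_path))
    cells <- readLines(cells_path)
    genes <- readLines(genes_path)
    if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
      stop("dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
           " but ", length(cells), " cells / ", length(genes),
           " genes were supplied")
    }
    dimnames(m) <- list(cells, genes)
  } else {
    df <- utils::read.delim(matrix_path, row.names = 1, check.names = FALSE)
    m <- as_dgc(Matrix::Matrix(as.matrix(df), sparse = TRUE))
  }
  if (any(m@x < 0) || any(m@x != round(m@x))) {
    stop("expression counts must be non-negative integers")
  }
  m
}

#' Write a cell-by-gene matrix as MatrixMarket triplet plus name files
#'
#' @param expr cells-by-genes matrix with dimnames.
#' @param matrix_path,cells_path,genes_path output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(expr, matrix_path, cells_path, genes_path) {
  Matrix::writeMM(as_dgc(expr), matrix_path)
  writeLines(rownames(expr), cells_path)
  writeLines(colnames(expr), genes_path)
  invisible(matrix_path)
}

#' Fold reads into molecules
#'
#' Reads carrying the same cell label, UMI and gene are PCR copies of one
#' captured mRNA molecule and are folded into a single molecule. The
#' molecule count of a (cell, gene) pair is therefore the number of
#' distinct UMIs observed for it.
#'
#' @param reads data frame with columns `cell_label`, `umi`, `gene`
#'   (one row per sequenced read).
#' @return data frame with columns `cell_label`, `gene`, `molecule_count`.
#' @export
fold_molecules <- function(reads) {
  if (nrow(reads) == 0L) {
    return(data.frame(cell_label = character(), gene = character(),
                      molecule_count = integer()))
  }
  stopifnot(all(c("cell_label", "umi", "gene") %in% names(reads)),
            all(nzchar(reads$umi)))
  u <- unique(reads[, c("cell_label", "gene", "umi")])
  agg <- stats::aggregate(list(molecule_count = u$umi),
                          by = list(cell_label = u$cell_label, gene = u$gene),
                          FUN = length)
  agg <- agg[order(agg$cell_label, agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  agg$molecule_count <- as.integer(agg$molecule_count)
  agg
}

hamming1 <- function(a, b) {
  # both are equal-length strings; TRUE if they differ at exactly one position
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  sum(av != bv) == 1L
}

collapse_group <- function(umis) {
  # umis: character vector of read-level UMIs for one (cell, gene) group.
  # Directional merge: a UMI within Hamming distance 1 of a strictly
  # more-abundant UMI is relabelled to it; ties are never merged. Repeated
  # to a fixpoint so the operation is idempotent on its own output.
  if (length(unique(nchar(umis))) > 1L) {
    stop("unequal UMI lengths within a (cell, gene) group")
  }
  repeat {
    tab <- table(umis)
    uniq <- names(tab)[order(-as.integer(tab), names(tab))]
    cnt <- as.integer(tab[uniq])
    if (length(uniq) < 2L) return(umis)
    map <- stats::setNames(uniq, uniq)
    for (i in seq_along(uniq)[-1L]) {
      for (j in seq_len(i - 1L)) {
        if (cnt[j] > cnt[i] && hamming1(uniq[i], uniq[j])) {
          map[uniq[i]] <- uniq[j]
          break
        }
      }
    }
    if (all(map == names(map))) return(umis)
    umis <- unname(map[umis])
  }
}

#' Collapse sequencing errors in UMIs by directional Hamming-1 merging
#'
#' Within each (cell label, gene) group, any UMI lying within Hamming
#' distance 1 of a strictly more-abundant UMI is relabelled to that UMI
#' (most-abundant candidate first; abundance ties are never merged). The
#' merge is applied until stable, so the operation is idempotent. This is
#' a simplified, open substitution-error correction for UMI counts.
#'
#' @param reads data frame with columns `cell_label`, `umi`, `gene`; all
#'   UMIs within a (cell_label, gene) group must share one length.
#' @return `reads` with corrected `umi` values, original row order.
#' @export
collapse_umis_hamming1 <- function(reads) {
  if (nrow(reads) == 0L) return(reads)
  stopifnot(all(c("cell_label", "umi", "gene") %in% names(reads)))
  grp <- paste0(reads$cell_label, "\r", reads$gene)
  reads$umi <- stats::ave(reads$umi, grp, FUN = collapse_group)
  reads
}
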