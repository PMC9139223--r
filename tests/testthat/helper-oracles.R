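# Independent oracles and small fixture builders used across the suite.

# Direct element-by-element summation of -sum(p log p); deliberately a
# plain loop, independent of the vectorized implementation.
shannon_oracle <- function(x) {
  total <- 0
  for (v in x) total <- total + v
  h <- 0
  for (v in x) {
    if (v > 0) {
      p <- v / total
      h <- h - p * log(p)
    }
  }
  h
}

# Brute-force molecule count: number of distinct (cell, gene, umi) triples
# per (cell, gene), via string keys and table().
fold_oracle <- function(reads) {
  triples <- unique(paste(reads$cell_label, reads$gene, reads$umi,
                          sep = "\t"))
  pairs <- sub("\t[^\t]*$", "", triples)
  table(pairs)
}

# Independent directional Hamming-1 merge for a single UMI group, written
# over split character vectors rather than utf8 codes.
hamming_oracle <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

collapse_oracle <- function(umis) {
  repeat {
    counts <- table(umis)
    ord <- names(counts)[order(-as.vector(counts), names(counts))]
    changed <- FALSE
    for (u in rev(ord)) {
      for (v in ord) {
        if (counts[v] > counts[u] && hamming_oracle(u, v) == 1) {
          umis[umis == u] <- v
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
    if (!changed) return(umis)
  }
}

# Chain-record builder for hand-constructed cases.
rec <- function(cell_id, locus, v_call, j_call, junction_aa,
                molecule_count = 1L) {
  data.frame(cell_id = cell_id, locus = locus, v_call = v_call,
             j_call = j_call, junction_aa = junction_aa,
             molecule_count = as.integer(molecule_count),
             read_count = as.integer(molecule_count),
             stringsAsFactors = FALSE)
}

# Small dense expression matrix with dimnames.
expr_matrix <- function(counts, cells, genes) {
  m <- matrix(as.integer(counts), nrow = length(cells),
              dimnames = list(cells, genes))
  pairrep:::as_dgc(Matrix::Matrix(m, sparse = TRUE))
}

fixture_catalog_path <- function() {
  system.file("extdata", "imgt_fixture.tsv", package = "pairrep",
              mustWork = TRUE)
}

write_airr <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}
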