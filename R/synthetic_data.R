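# Synthetic paired single-cell TCR + targeted-expression generator with
# known ground truth. Emulates a microwell-based capture of ~1e4 cells per
# sample: cells drawn from a clone frequency law, each clone a fixed paired
# (TRA, TRB) identity over the functional segment catalog, marker-positive
# subsets with negative-binomial UMI counts, and planted log2 fold-change
# effects on panel genes.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Segments the study found dominant; placed first in the default skewed
# usage profiles so simulated samples reproduce realistic rank structure.
DOMINANT_SEGMENTS <- list(
  TRA_V = c("TRAV9-2", "TRAV12-1", "TRAV12-3", "TRAV13-1", "TRAV17"),
  TRA_J = c("TRAJ9", "TRAJ20", "TRAJ29", "TRAJ34", "TRAJ49"),
  TRB_V = c("TRBV9", "TRBV19", "TRBV6-5", "TRBV12-3", "TRBV28"),
  TRB_J = c("TRBJ2-1", "TRBJ2-7", "TRBJ1-2", "TRBJ2-3", "TRBJ1-1"))

# Targeted T-cell panel: markers, the signature genes reported up/down in
# CD8+ and FOXP3+ subsets, padded to 100 genes with neutral panel genes.
default_panel_genes <- function() {
  named <- c("CD8A", "FOXP3", "PRF1", "GZMH", "ITGB2", "NKG7", "CTSW",
             "CST7", "SELL", "SELPLG", "GNLY", "CX3CR1", "CD4", "CD5",
             "CD7", "CD27", "CD69", "IL32", "HLA-A", "HLA-DMA", "IL4R",
             "TNFRSF4", "LIF", "TRIB2", "PRDM1")
  c(named, sprintf("PNL%03d", seq_len(100 - length(named))))
}

default_usage_profile <- function(segments, favored = character(),
                                  decay = 0.9) {
  ordered <- c(intersect(favored, segments), setdiff(segments, favored))
  w <- decay^(seq_along(ordered) - 1)
  stats::setNames(w / sum(w), ordered)
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic repertoire and
#' expression generator. Defaults emulate one captured sample: 1e4 cells,
#' 200 clones under a flat Dirichlet clone-frequency law, usage profiles
#' skewed toward the segments dominant in patient repertoires, CDR3
#' lengths spanning 8-20 amino acids, a CD8+ fraction of 25% and a FOXP3+
#' fraction of 5% with the FOXP3+ subset drawn from a restricted clone
#' pool (so subset diversity is genuinely lower than bulk), and planted
#' 4-fold effects on the CD8 signature genes.
#'
#' @param n_cells number of captured cells.
#' @param n_clones number of distinct paired clones.
#' @param clone_law list: `law = "dirichlet"` with `alpha`, or
#'   `law = "geometric"` with ratio `r` in (0, 1).
#' @param v_usage,j_usage named lists (`TRA`, `TRB`) of probability
#'   vectors over segment names; defaults derive from the functional
#'   segments of `catalog`.
#' @param cdr3_length_range integer interval of CDR3 amino-acid lengths.
#' @param marker_positive_fraction named fractions in (0, 1) of
#'   marker-positive cells.
#' @param marker_clone_fraction named fractions: each marker's positive
#'   cells are drawn from cells whose clone index lies in the first such
#'   fraction of clones (nested clonal support; 1 = unrestricted).
#' @param marker_count negative-binomial law (`mean`, `size`) for marker
#'   UMI counts in positive cells (zero-truncated).
#' @param background_mean,background_size negative-binomial law for
#'   non-marker panel genes.
#' @param de_log_fc named numeric of planted log2 fold changes applied to
#'   gene means when simulating a case sample.
#' @param chain_dropout probability that a cell's TRA (or TRB) chain is
#'   not recovered, independently per chain.
#' @param panel_genes character vector of panel gene ids.
#' @param seed integer seed; all generator output is a pure function of
#'   the configuration including this seed.
#' @param catalog segment catalog used for the default usage profiles.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_cells = 10000, n_clones = 200,
                       clone_law = list(law = "dirichlet", alpha = 1),
                       v_usage = NULL, j_usage = NULL,
                       cdr3_length_range = c(8L, 20L),
                       marker_positive_fraction = c(CD8A = 0.25,
                                                    FOXP3 = 0.05),
                       marker_clone_fraction = c(CD8A = 0.6, FOXP3 = 0.15),
                       marker_count = list(mean = 2, size = 2),
                       background_mean = 0.3, background_size = 2,
                       de_log_fc = c(PRF1 = 2, GZMH = 2, ITGB2 = 2,
                                     NKG7 = 2, CTSW = 2, CD4 = -2,
                                     CD7 = -2, CD5 = -2, CD27 = -2),
                       chain_dropout = 0.1,
                       panel_genes = default_panel_genes(),
                       seed = 1L, catalog = default_catalog()) {
  stopifnot(n_cells >= 1, n_clones >= 1,
            clone_law$law %in% c("dirichlet", "geometric"),
            length(cdr3_length_range) == 2L,
            cdr3_length_range[1] >= 1,
            cdr3_length_range[2] >= cdr3_length_range[1],
            all(marker_positive_fraction > 0),
            all(marker_positive_fraction < 1),
            chain_dropout >= 0, chain_dropout < 1,
            all(names(marker_positive_fraction) %in% panel_genes))
  fun <- filter_segments(catalog, "functional")
  if (is.null(v_usage)) {
    v_usage <- list(
      TRA = default_usage_profile(catalog_segments(fun, "TRA", "V"),
                                  DOMINANT_SEGMENTS$TRA_V),
      TRB = default_usage_profile(catalog_segments(fun, "TRB", "V"),
                                  DOMINANT_SEGMENTS$TRB_V))
  }
  if (is.null(j_usage)) {
    j_usage <- list(
      TRA = default_usage_profile(catalog_segments(fun, "TRA", "J"),
                                  DOMINANT_SEGMENTS$TRA_J),
      TRB = default_usage_profile(catalog_segments(fun, "TRB", "J"),
                                  DOMINANT_SEGMENTS$TRB_J))
  }
  for (prof in c(v_usage, j_usage)) {
    stopifnot(abs(sum(prof) - 1) < 1e-8, all(prof >= 0),
              !is.null(names(prof)))
  }
  marker_clone_fraction <- marker_clone_fraction[
    names(marker_positive_fraction)]
  marker_clone_fraction[is.na(marker_clone_fraction)] <- 1
  names(marker_clone_fraction) <- names(marker_positive_fraction)
  structure(list(n_cells = as.integer(n_cells),
                 n_clones = as.integer(n_clones), clone_law = clone_law,
                 v_usage = v_usage, j_usage = j_usage,
                 cdr3_length_range = as.integer(cdr3_length_range),
                 marker_positive_fraction = marker_positive_fraction,
                 marker_clone_fraction = marker_clone_fraction,
                 marker_count = marker_count,
                 background_mean = background_mean,
                 background_size = background_size,
                 de_log_fc = de_log_fc, chain_dropout = chain_dropout,
                 panel_genes = panel_genes, seed = as.integer(seed)),
            class = "sim_config")
}

draw_clone_frequencies <- function(config) {
  k <- config$n_clones
  p <- switch(config$clone_law$law,
              dirichlet = {
                g <- stats::rgamma(k, shape = config$clone_law$alpha %||% 1)
                g / sum(g)
              },
              geometric = {
                r <- config$clone_law$r %||% 0.95
                w <- r^(seq_len(k) - 1)
                w / sum(w)
              })
  if (any(p <= 0)) p <- (p + .Machine$double.eps) / sum(p + .Machine$double.eps)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_cdr3 <- function(n, len_range) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  vapply(lens, function(l) {
    paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = "")
  }, character(1))
}

draw_clone_identities <- function(config) {
  k <- config$n_clones
  draw <- function(prof, n) sample(names(prof), n, replace = TRUE,
                                   prob = prof)
  ids <- data.frame(
    clone = seq_len(k),
    tra_v = draw(config$v_usage$TRA, k),
    cdr3_a = random_cdr3(k, config$cdr3_length_range),
    tra_j = draw(config$j_usage$TRA, k),
    trb_v = draw(config$v_usage$TRB, k),
    cdr3_b = random_cdr3(k, config$cdr3_length_range),
    trb_j = draw(config$j_usage$TRB, k),
    stringsAsFactors = FALSE)
  # clone identities must not collide, otherwise the plug-in entropy over
  # clonotypes would not match the configured clone law
  repeat {
    key <- paste(ids$tra_v, ids$cdr3_a, ids$tra_j, ids$trb_v, ids$cdr3_b,
                 ids$trb_j)
    dup <- duplicated(key)
    if (!any(dup)) break
    n <- sum(dup)
    ids$cdr3_a[dup] <- random_cdr3(n, config$cdr3_length_range)
    ids$cdr3_b[dup] <- random_cdr3(n, config$cdr3_length_range)
  }
  ids
}

#' Simulate a paired single-cell TCR repertoire
#'
#' Each cell draws a clone from the configured clone-frequency law; every
#' clone carries a fixed paired identity (TRA V/CDR3/J and TRB V/CDR3/J)
#' with segments drawn once from the usage profiles and CDR3 letters
#' uniform over the amino-acid alphabet. Per-cell chain molecule counts
#' are 1 + Poisson(2); chains are lost independently with probability
#' `chain_dropout`. Marker-positive cell sets are drawn here (optionally
#' from a restricted clone pool) and recorded in the ground truth used by
#' [simulate_expression()]. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `records` (chain-record data frame) and `truth`
#'   (`sim_truth`: `clone_frequencies`, `clone_identities`,
#'   `true_shannon`, `cell_clone`, `cell_subset_labels`).
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- draw_clone_frequencies(config)
  ids <- draw_clone_identities(config)
  n <- config$n_cells
  cell_id <- sprintf("cell%06d", seq_len(n))
  clone_of <- sample.int(config$n_clones, n, replace = TRUE, prob = p)
  keep_a <- stats::rbinom(n, 1, 1 - config$chain_dropout) == 1
  keep_b <- stats::rbinom(n, 1, 1 - config$chain_dropout) == 1
  mol_a <- 1L + stats::rpois(n, 2)
  mol_b <- 1L + stats::rpois(n, 2)
  rec_a <- chain_records(cell_id[keep_a], "TRA",
                         ids$tra_v[clone_of[keep_a]],
                         ids$tra_j[clone_of[keep_a]],
                         ids$cdr3_a[clone_of[keep_a]], mol_a[keep_a])
  rec_b <- chain_records(cell_id[keep_b], "TRB",
                         ids$trb_v[clone_of[keep_b]],
                         ids$trb_j[clone_of[keep_b]],
                         ids$cdr3_b[clone_of[keep_b]], mol_b[keep_b])
  records <- rbind(rec_a, rec_b)
  records <- records[order(records$cell_id, records$locus,
                           method = "radix"), , drop = FALSE]
  rownames(records) <- NULL
  subsets <- list()
  for (m in names(config$marker_positive_fraction)) {
    frac <- config$marker_positive_fraction[[m]]
    clone_frac <- config$marker_clone_fraction[[m]]
    eligible <- cell_id[clone_of <= ceiling(clone_frac * config$n_clones)]
    n_pos <- round(frac * n)
    if (length(eligible) < n_pos) {
      warning("marker ", m, ": restricted clone pool smaller than the ",
              "requested positive fraction; using all eligible cells")
      n_pos <- length(eligible)
    }
    subsets[[m]] <- sort(sample(eligible, n_pos))
  }
  truth <- structure(list(clone_frequencies = p, clone_identities = ids,
                          true_shannon = -sum(p[p > 0] * log(p[p > 0])),
                          cell_clone = data.frame(cell_id = cell_id,
                                                  clone = clone_of),
                          cell_subset_labels = subsets,
                          config = config),
                     class = "sim_truth")
  list(records = records, truth = truth)
}

#' True Shannon index of a simulated repertoire
#'
#' @param truth a `sim_truth` from [simulate_repertoire()].
#' @return the exact H' of the generating clone-frequency vector.
#' @export
true_shannon <- function(truth) {
  p <- truth$clone_frequencies
  -sum(p[p > 0] * log(p[p > 0]))
}

rnbinom_pos <- function(n, mu, size) {
  # zero-truncated negative binomial by rejection
  x <- stats::rnbinom(n, mu = mu, size = size)
  while (any(x == 0)) {
    i <- x == 0
    x[i] <- stats::rnbinom(sum(i), mu = mu, size = size)
  }
  x
}

#' Simulate a targeted panel expression matrix
#'
#' Marker genes receive zero-truncated negative-binomial UMI counts in
#' exactly the ground-truth positive cells and zero elsewhere; the other
#' panel genes receive background negative-binomial counts. When `case`
#' is `TRUE` every gene mean is scaled by `2^de_log_fc[gene]`, planting
#' the configured fold changes. Reproducible from the configuration seed
#' (offset so repertoire and expression draws are independent).
#'
#' @param config a [sim_config()].
#' @param truth the matching `sim_truth` from [simulate_repertoire()].
#' @param case logical: apply the planted fold changes?
#' @return sparse cells-by-genes count matrix.
#' @export
simulate_expression <- function(config, truth, case = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  # seed offset keeps expression draws independent of the repertoire draws;
  # it is deliberately not a function of `case`, so zero planted effects
  # give byte-identical case and control matrices
  set.seed(config$seed + 200003L)
  cells <- truth$cell_clone$cell_id
  genes <- config$panel_genes
  n <- length(cells)
  markers <- names(config$marker_positive_fraction)
  lfc <- stats::setNames(rep(0, length(genes)), genes)
  if (case) lfc[names(config$de_log_fc)] <- config$de_log_fc
  counts <- matrix(0L, n, length(genes), dimnames = list(cells, genes))
  for (g in genes) {
    if (g %in% markers) {
      pos <- match(truth$cell_subset_labels[[g]], cells)
      counts[pos, g] <- rnbinom_pos(length(pos),
                                    mu = config$marker_count$mean * 2^lfc[[g]],
                                    size = config$marker_count$size)
    } else {
      counts[, g] <- stats::rnbinom(n,
                                    mu = config$background_mean * 2^lfc[[g]],
                                    size = config$background_size)
    }
  }
  as_dgc(Matrix::Matrix(counts, sparse = TRUE))
}

#' Expand chain records into read-level records with UMIs
#'
#' Utility for exercising the molecule-folding and UMI error-correction
#' steps: every molecule of every chain record receives a distinct random
#' UMI, replicated `reads_per_molecule` times, and an optional per-read
#' single-base UMI substitution at rate `error_rate`.
#'
#' @param records chain-record data frame.
#' @param reads_per_molecule PCR copies per molecule.
#' @param umi_length UMI length in bases.
#' @param error_rate per-read probability of one substituted UMI base.
#' @param seed integer seed.
#' @return read-level data frame: `cell_label`, `umi`, `gene`, `read_id`.
#' @export
simulate_reads <- function(records, reads_per_molecule = 3, umi_length = 8,
                           error_rate = 0, seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n_mol <- sum(records$molecule_count)
  umis <- vapply(seq_len(n_mol), function(i) {
    paste(sample(bases, umi_length, replace = TRUE), collapse = "")
  }, character(1))
  idx <- rep(seq_len(nrow(records)), records$molecule_count)
  reads <- data.frame(
    cell_label = rep(records$cell_id[idx], each = reads_per_molecule),
    umi = rep(umis, each = reads_per_molecule),
    gene = rep(records$v_call[idx], each = reads_per_molecule),
    stringsAsFactors = FALSE)
  if (error_rate > 0) {
    hit <- which(stats::runif(nrow(reads)) < error_rate)
    for (i in hit) {
      pos <- sample.int(umi_length, 1)
      u <- strsplit(reads$umi[i], "")[[1]]
      u[pos] <- sample(setdiff(bases, u[pos]), 1)
      reads$umi[i] <- paste(u, collapse = "")
    }
  }
  reads$read_id <- sprintf("read%07d", seq_len(nrow(reads)))
  reads
}
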