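# End-to-end report driver: wires catalog filtering, repertoire
# statistics, gating and fold-change ranking into one deterministic
# report bundle per sample.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(v_segment = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  write_tsv(df, path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full repertoire report for one sample
#'
#' Produces, under `out_dir`: V and J usage tables for both loci, V-J
#' pairing matrices, a diversity table (bulk and, when an expression
#' matrix is supplied, the CD8+ and FOXP3+ subsets, for TRA and TRB), the
#' top-n paired clonotype table (bulk and per gated subset), top/bottom
#' fold-change tables against a reference sample when one is supplied,
#' and a JSON run manifest. All outputs are deterministic functions of
#' the inputs; clonotype frequencies are printed to one decimal place.
#'
#' @param records chain-record data frame (or path to an AIRR TSV).
#' @param out_dir output directory, created if needed.
#' @param expression optional cells-by-genes count matrix; enables gated
#'   subset statistics.
#' @param ref_expression optional reference count matrix; enables the
#'   fold-change tables (the reference is gated with the same rule).
#' @param catalog segment catalog.
#' @param keep functionality classes counted.
#' @param weight_basis weighting for usage/pairing tables.
#' @param entity diversity entity (see [repertoire_diversity()]).
#' @param gates named list of `list(marker =, min_umi =)` gate rules.
#' @param top_n clonotypes and genes per report table.
#' @param pseudocount fold-change stabilizer.
#' @return invisibly, a named list of the files written.
#' @export
run_report <- function(records, out_dir, expression = NULL,
                       ref_expression = NULL, catalog = default_catalog(),
                       keep = "functional", weight_basis = "molecules",
                       entity = "cdr3_aa",
                       gates = list(
                         `CD8+` = list(marker = "CD8A", min_umi = 1),
                         `FOXP3+` = list(marker = "FOXP3", min_umi = 1)),
                       top_n = 10, pseudocount = 1) {
  if (is.character(records)) {
    records <- run_stage("read_rearrangements", read_rearrangements(records))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (locus in c("TRA", "TRB")) {
    for (ty in c("V", "J")) {
      u <- run_stage(paste0("usage_", locus, "_", ty),
                     segment_usage(records, locus, ty, catalog, keep,
                                   weight_basis))
      paths[[paste0("usage_", locus, "_", ty)]] <-
        write_tsv(data.frame(label = u$label, count = u$count,
                             percent = round(u$percent, 4)),
                  file.path(out_dir, paste0("usage_", locus, "_", ty,
                                            ".tsv")))
    }
    pm <- run_stage(paste0("pairing_", locus),
                    vj_pairing(records, locus, catalog, keep, weight_basis))
    paths[[paste0("pairing_", locus)]] <-
      write_matrix_tsv(round(pm$percent, 6),
                       file.path(out_dir, paste0("pairing_", locus,
                                                 ".tsv")))
  }
  gate_sets <- list()
  if (!is.null(expression)) {
    for (g in names(gates)) {
      gate_sets[[g]] <- run_stage(
        paste0("gate_", g),
        gate_cells(expression, gates[[g]]$marker, gates[[g]]$min_umi))
    }
  }
  div <- data.frame(subset = character(), locus = character(),
                    entity = character(), shannon = numeric(),
                    n_cells = integer())
  for (locus in c("TRA", "TRB")) {
    div <- rbind(div, data.frame(
      subset = "bulk", locus = locus, entity = entity,
      shannon = run_stage("diversity",
                          repertoire_diversity(records, entity, locus)),
      n_cells = length(unique(records$cell_id))))
    for (g in names(gate_sets)) {
      sub <- subset_records(records, gate_sets[[g]])
      h <- if (nrow(sub) == 0L) NA_real_ else
        run_stage(paste0("diversity_", g),
                  repertoire_diversity(sub, entity, locus))
      div <- rbind(div, data.frame(subset = g, locus = locus,
                                   entity = entity, shannon = h,
                                   n_cells = length(gate_sets[[g]])))
    }
  }
  div$shannon <- round(div$shannon, 4)
  paths$diversity <- write_tsv(div, file.path(out_dir, "diversity.tsv"))
  clone_report <- function(recs, file) {
    asm <- run_stage("clonotypes", assemble_clonotypes(recs))
    top <- top_clonotypes(asm, top_n)
    out <- data.frame(clone_id = top$clone_id,
                      frequency_percent = sprintf("%.1f",
                                                  top$frequency_percent),
                      top[c("tra_v", "cdr3_a", "tra_j", "trb_v", "cdr3_b",
                            "trb_j", "n_cells")])
    write_tsv(out, file.path(out_dir, file))
  }
  paths$clonotypes_bulk <- clone_report(records, "clonotypes_bulk.tsv")
  for (g in names(gate_sets)) {
    tag <- gsub("[^A-Za-z0-9]", "", g)
    paths[[paste0("clonotypes_", tag)]] <-
      clone_report(subset_records(records, gate_sets[[g]]),
                   paste0("clonotypes_", tag, ".tsv"))
  }
  if (!is.null(ref_expression) && !is.null(expression)) {
    for (g in names(gates)) {
      tag <- gsub("[^A-Za-z0-9]", "", g)
      ref_cells <- run_stage(
        paste0("gate_ref_", g),
        gate_cells(ref_expression, gates[[g]]$marker, gates[[g]]$min_umi))
      rk <- run_stage(paste0("de_", g),
                      rank_fold_changes(expression, ref_expression,
                                        gate_sets[[g]], ref_cells,
                                        pseudocount = pseudocount))
      tops <- top_de(rk, top_n)
      fmt <- function(df) data.frame(
        gene_id = df$gene_id, log2_fc = round(df$log2_fc, 4),
        mean_sample = round(df$mean_sample, 4),
        mean_ref = round(df$mean_ref, 4))
      paths[[paste0("de_up_", tag)]] <-
        write_tsv(fmt(tops$up), file.path(out_dir,
                                          paste0("de_up_", tag, ".tsv")))
      paths[[paste0("de_down_", tag)]] <-
        write_tsv(fmt(tops$down),
                  file.path(out_dir, paste0("de_down_", tag, ".tsv")))
    }
  }
  manifest <- list(
    tool = "pairrep",
    version = as.character(utils::packageVersion("pairrep")),
    parameters = list(keep = keep, weight_basis = weight_basis,
                      entity = entity, top_n = top_n,
                      pseudocount = pseudocount,
                      gates = gates),
    n_records = nrow(records),
    n_cells = length(unique(records$cell_id)),
    files = vapply(paths, basename, character(1)))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  paths$manifest <- manifest_path
  invisible(paths)
}
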