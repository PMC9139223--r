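catalog <- load_catalog(fixture_catalog_path())

test_that("segment usage excludes filtered classes from the denominator", {
  records <- rbind(rec("c1", "TRA", "AV9-2", "AJ9", "AVA", 1),
                   rec("c2", "TRA", "AV9-2", "AJ20", "AVB", 1),
                   rec("c3", "TRA", "AV17", "AJ29", "AVC", 1),
                   rec("c4", "TRA", "AV11", "AJ34", "AVD", 1))  # pseudogene
  u <- segment_usage(records, "TRA", "V", catalog)
  expect_setequal(u$label, c("TRAV9-2", "TRAV17"))
  expect_equal(u$percent[u$label == "TRAV9-2"], 200 / 3, tolerance = 1e-12)
  expect_equal(u$percent[u$label == "TRAV17"], 100 / 3, tolerance = 1e-12)
  expect_equal(sum(u$percent), 100, tolerance = 1e-9)

  # the pseudogene is counted when its class is kept
  u2 <- segment_usage(records, "TRA", "V", catalog,
                      keep = c("functional", "pseudogene"))
  expect_equal(u2$percent[u2$label == "TRAV11"], 25)

  # single record: 100% for its segment
  u3 <- segment_usage(rec("c1", "TRB", "TRBV9", "TRBJ2-1", "ASS"), "TRB",
                      "V", catalog)
  expect_equal(u3$percent, 100)

  # no records: explicitly empty table
  u4 <- segment_usage(records[0, ], "TRA", "V", catalog)
  expect_equal(nrow(u4), 0)
})

test_that("segment usage supports molecule, read and cell weighting", {
  records <- rbind(rec("c1", "TRA", "TRAV1-1", "TRAJ4", "AVA", 4),
                   rec("c1", "TRA", "TRAV1-1", "TRAJ4", "AVB", 2),
                   rec("c2", "TRA", "TRAV2", "TRAJ4", "AVC", 2))
  records$read_count <- c(8L, 2L, 2L)
  mol <- segment_usage(records, "TRA", "V", catalog)
  expect_equal(mol$percent[mol$label == "TRAV1-1"], 75)
  rds <- segment_usage(records, "TRA", "V", catalog,
                       weight_basis = "reads")
  expect_equal(rds$percent[rds$label == "TRAV1-1"], 1000 / 12,
               tolerance = 1e-12)
  cel <- segment_usage(records, "TRA", "V", catalog,
                       weight_basis = "cells")
  expect_equal(cel$percent[cel$label == "TRAV1-1"], 50)

  # min_count = 0 keeps the full filtered catalog, zeros included
  full <- segment_usage(records, "TRA", "V", catalog, min_count = 0)
  expect_equal(nrow(full), sum(catalog$locus == "TRA" &
                                 catalog$segment_type == "V" &
                                 catalog$functionality == "functional"))
  expect_true(all(full$percent[!full$label %in%
                                 c("TRAV1-1", "TRAV2")] == 0))
})

test_that("segments missing from the catalog are kept with a warning", {
  records <- rec("c1", "TRA", "TRAV99", "TRAJ4", "AVA", 1)
  expect_warning(u <- segment_usage(records, "TRA", "V", catalog),
                 "TRAV99")
  expect_equal(u$percent[u$label == "TRAV99"], 100)
})

test_that("V-J pairing percentages and marginals behave", {
  records <- rbind(rec("c1", "TRA", "V27", "J43", "AVA", 1),
                   rec("c2", "TRA", "V27", "J43", "AVB", 1),
                   rec("c3", "TRA", "V27", "J43", "AVC", 1),
                   rec("c4", "TRA", "V17", "J13", "AVD", 1))
  pm <- vj_pairing(records, "TRA", catalog)
  expect_equal(pm$percent["TRAV27", "TRAJ43"], 75)
  expect_equal(pm$percent["TRAV17", "TRAJ13"], 25)
  expect_equal(sum(pm$percent), 100, tolerance = 1e-9)
  expect_equal(sum(pm$percent > 0), 2)

  # one record: a one-hot matrix
  pm1 <- vj_pairing(records[1, ], "TRA", catalog)
  expect_equal(sum(pm1$percent), 100)
  expect_equal(sum(pm1$percent > 0), 1)

  # marginal conservation against usage vectors over the same filters
  uv <- segment_usage(records, "TRA", "V", catalog, min_count = 0)
  uj <- segment_usage(records, "TRA", "J", catalog, min_count = 0)
  expect_equal(rowSums(pm$percent),
               stats::setNames(uv$percent, uv$label)[pm$v_labels],
               tolerance = 1e-12)
  expect_equal(colSums(pm$percent),
               stats::setNames(uj$percent, uj$label)[pm$j_labels],
               tolerance = 1e-12)
})

test_that("shannon_index matches hand values and rejects bad input", {
  expect_equal(shannon_index(5), 0)
  expect_equal(shannon_index(rep(1, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.039721,
               tolerance = 1e-6)
  expect_equal(shannon_index(c(2, 1, 0, 1)), shannon_index(c(2, 1, 1)))
  expect_error(shannon_index(c(0, 0)), "positive")
  expect_error(shannon_index(c(-1, 2)), "non-negative")
  expect_error(shannon_index(numeric()), "non-negative")
})

test_that("shannon_index is permutation- and scale-invariant and concave", {
  set.seed(11)
  for (i in 1:10) {
    x <- stats::rgamma(50, 1)
    expect_equal(shannon_index(x), shannon_index(sample(x)))
    expect_equal(shannon_index(x), shannon_index(x / sum(x)),
                 tolerance = 1e-12)
    expect_equal(shannon_index(x), shannon_index(1000 * x),
                 tolerance = 1e-12)
  }
  # splitting one clone into two equal halves strictly increases H'
  x <- c(0.4, 0.3, 0.3)
  split <- c(0.2, 0.2, 0.3, 0.3)
  expect_gt(shannon_index(split), shannon_index(x))
  # uniform maximum: exactly log(S) well past typical repertoire sizes
  for (S in c(10, 1000, 1e5)) {
    expect_equal(shannon_index(rep(1, S)), log(S), tolerance = 1e-12)
    expect_lte(shannon_index(stats::rgamma(S, 1)), log(S))
  }
})

test_that("paired clonotype assembly selects dominant chains per cell", {
  records <- rbind(
    rec("c1", "TRA", "V27", "J43", "AGAISNNDMR", 5),
    rec("c1", "TRB", "V9", "J2-1", "ASSVVGSGTDEQF", 4),
    rec("c2", "TRA", "V17", "J13", "ATDSGGYQKVT", 2))  # TRA only
  asm <- assemble_clonotypes(records)
  expect_equal(asm$n_paired, 1)
  expect_equal(asm$unpaired, "c2")
  expect_equal(asm$clonotypes$tra_v, "TRAV27")
  expect_equal(asm$clonotypes$cdr3_a, "AGAISNNDMR")
  expect_equal(asm$clonotypes$trb_v, "TRBV9")
  expect_equal(asm$clonotypes$cdr3_b, "ASSVVGSGTDEQF")
  expect_equal(asm$clonotypes$trb_j, "TRBJ2-1")
  expect_equal(asm$clonotypes$frequency_percent, 100)

  # the more-abundant of two same-locus chains wins
  two <- rbind(rec("c1", "TRA", "TRAV1-1", "TRAJ4", "AAA", 5),
               rec("c1", "TRA", "TRAV2", "TRAJ5", "BBB", 2),
               rec("c1", "TRB", "TRBV9", "TRBJ2-1", "CCC", 1))
  asm2 <- assemble_clonotypes(two)
  expect_equal(asm2$clonotypes$tra_v, "TRAV1-1")

  # abundance ties break on the smaller junction, then v_call
  tie <- rbind(rec("c1", "TRA", "TRAV2", "TRAJ4", "ZZZ", 3),
               rec("c1", "TRA", "TRAV1-1", "TRAJ4", "AAA", 3),
               rec("c1", "TRB", "TRBV9", "TRBJ2-1", "CCC", 1))
  expect_equal(assemble_clonotypes(tie)$clonotypes$cdr3_a, "AAA")
})

test_that("top clonotype tables rank, tie-break and round like reports", {
  # 10 of 127 paired cells sharing one clonotype prints as 7.9%
  cells <- c(sprintf("s%03d", 1:127))
  big <- do.call(rbind, lapply(1:127, function(i) {
    shared <- i <= 10
    rbind(rec(cells[i], "TRA", "TRAV27", "TRAJ43",
              if (shared) "AGAISNNDMR" else sprintf("AG%03d", i), 1),
          rec(cells[i], "TRB", "TRBV9", "TRBJ2-1",
              if (shared) "ASSVVGSGTDEQF" else sprintf("AS%03d", i), 1))
  }))
  asm <- assemble_clonotypes(big)
  top <- top_clonotypes(asm, 1)
  expect_equal(top$n_cells, 10L)
  expect_equal(sprintf("%.1f", top$frequency_percent), "7.9")

  # n beyond the table returns everything
  expect_equal(nrow(top_clonotypes(asm, 1e6)), nrow(asm$clonotypes))

  # frequencies are non-increasing and bounded by 100
  t10 <- top_clonotypes(asm, 10)
  expect_true(all(diff(t10$frequency_percent) <= 0))
  expect_true(all(t10$frequency_percent <= 100))

  # equal-count clonotypes order deterministically by their identity
  pair <- rbind(rec(c("a1", "a2"), "TRA", "TRAV2", "TRAJ4", "BBB", 1),
                rec(c("a1", "a2"), "TRB", "TRBV9", "TRBJ2-1", "YYY", 1),
                rec(c("b1", "b2"), "TRA", "TRAV1-1", "TRAJ4", "AAA", 1),
                rec(c("b1", "b2"), "TRB", "TRBV9", "TRBJ2-1", "XXX", 1))
  t2 <- top_clonotypes(assemble_clonotypes(pair), 2)
  expect_equal(t2$tra_v, c("TRAV1-1", "TRAV2"))
  expect_error(top_clonotypes(asm, 0), ">= 1")
})

test_that("repertoire diversity is computed per entity", {
  records <- rbind(rec("c1", "TRA", "TRAV1-1", "TRAJ4", "AAA", 2),
                   rec("c2", "TRA", "TRAV1-1", "TRAJ4", "AAA", 2),
                   rec("c3", "TRA", "TRAV2", "TRAJ5", "BBB", 4),
                   rec(c("c1", "c2", "c3"), "TRB", "TRBV9", "TRBJ2-1",
                       "CCC", 1))
  # cdr3_aa on TRA: two species at 4 molecules each -> log 2
  expect_equal(repertoire_diversity(records, "cdr3_aa", "TRA"), log(2),
               tolerance = 1e-12)
  # single TRB species -> 0
  expect_equal(repertoire_diversity(records, "cdr3_aa", "TRB"), 0)
  expect_equal(repertoire_diversity(records, "vj_pair", "TRA"), log(2),
               tolerance = 1e-12)
  # clonotype entity: two paired clonotypes at 2:1 cells
  h <- repertoire_diversity(records, "clonotype")
  expect_equal(h, shannon_oracle(c(2, 1)), tolerance = 1e-12)
})
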