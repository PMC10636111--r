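test_that("pair enumeration reproduces the design counts", {
  m <- pairing_meta(14, 14, "INFANT_ORAL")
  p <- enumerate_pairs(m, "MILK", "INFANT_ORAL")
  expect_identical(attr(p, "n_related"), 14L)
  expect_identical(attr(p, "n_unrelated"), 182L)

  m2 <- pairing_meta(14, 13)   # one family missing the second sample type
  p2 <- enumerate_pairs(m2, "MILK", "MATERNAL_FAECES")
  expect_identical(attr(p2, "n_related"), 13L)
  expect_identical(attr(p2, "n_unrelated"), 169L)

  m3 <- pairing_meta(2, 2, "INFANT_FAECES")
  p3 <- enumerate_pairs(m3, "MILK", "INFANT_FAECES")
  expect_identical(attr(p3, "n_related"), 2L)
  expect_identical(attr(p3, "n_unrelated"), 2L)
})

test_that("pair totals match an exhaustive double loop", {
  set.seed(17)
  for (i in 1:5) {
    na <- sample(3:10, 1); nb <- sample(3:10, 1)
    m <- pairing_meta(na, nb, "INFANT_ORAL")
    p <- enumerate_pairs(m, "MILK", "INFANT_ORAL")
    a <- m[m$sample_type == "MILK", ]; b <- m[m$sample_type == "INFANT_ORAL", ]
    rel <- 0; unrel <- 0
    for (x in seq_len(nrow(a))) for (y in seq_len(nrow(b))) {
      if (a$sample_id[x] == b$sample_id[y]) next
      if (a$family_id[x] == b$family_id[y]) rel <- rel + 1 else unrel <- unrel + 1
    }
    expect_identical(attr(p, "n_related"), as.integer(rel))
    expect_identical(attr(p, "n_unrelated"), as.integer(unrel))
    expect_true(all(p$related == (p$family_a == p$family_b)))
    expect_false(any(p$sample_a == p$sample_b))
    expect_false(any(duplicated(paste(p$sample_a, p$sample_b))))
  }
})

test_that("replicates are rejected unless collapsed", {
  m <- pairing_meta(3, 3, "INFANT_ORAL")
  extra <- m[1, ]; extra$sample_id <- "F01_MILK_rep2"; extra$replicate <- 2L
  m_dup <- rbind(m, extra)
  expect_error(enumerate_pairs(m_dup, "MILK", "INFANT_ORAL"), ">1 sample")

  counts <- matrix(1L, nrow(m_dup), 2,
                   dimnames = list(m_dup$sample_id, c("x", "y")))
  counts["F01_MILK_rep2", ] <- c(5L, 0L)
  col <- collapse_replicates(asv_table(counts), m_dup)
  expect_identical(nrow(col$table), nrow(m))
  expect_identical(unname(col$table["F01_MILK", ]), c(6L, 1L))
  expect_silent(enumerate_pairs(col$meta, "MILK", "INFANT_ORAL"))
})

test_that("candidate genera require detection in both members of >= 2 related pairs", {
  ds <- tiny_dataset()
  pairs <- enumerate_pairs(ds$meta, "MILK", "INFANT_ORAL")
  # Streptococcus: both members of both related pairs; Rothia: only F02 pair
  expect_identical(select_candidate_genera(ds$table, ds$taxonomy, pairs),
                   "Streptococcus")
  expect_identical(
    select_candidate_genera(ds$table, ds$taxonomy, pairs, min_related_pairs = 1),
    c("Rothia", "Streptococcus"))
})

test_that("sharing status requires exact sequence identity", {
  ds <- tiny_dataset()
  pairs <- enumerate_pairs(ds$meta, "MILK", "INFANT_ORAL")
  calls <- classify_pair_sharing(pairs, "Streptococcus", ds$table, ds$records,
                                 ds$taxonomy)
  rel <- calls[calls$related, ]
  # F01: a1 in both with counts (5, 3) -> SHARED via a1
  expect_identical(rel$status[rel$family_a == "F01"], "SHARED")
  expect_identical(rel$shared_asv_ids[rel$family_a == "F01"], "a1")
  # F02: a2 in both -> SHARED
  expect_identical(rel$status[rel$family_a == "F02"], "SHARED")
  # unrelated pairs hold different Streptococcus ASVs (a1 vs a2, Hamming 1):
  # present in both but not identical
  unrel <- calls[!calls$related, ]
  expect_true(all(unrel$status == "PRESENT_NOT_SHARED"))

  rcalls <- classify_pair_sharing(pairs, "Rothia", ds$table, ds$records,
                                  ds$taxonomy)
  # Rothia absent from F01's infant oral sample
  expect_identical(rcalls$status[rcalls$related & rcalls$family_a == "F01"],
                   "ABSENT_IN_ONE_OR_BOTH")
})

test_that("sharing calls are symmetric and invariant to ASV relabeling", {
  ds <- tiny_dataset()
  pairs <- enumerate_pairs(ds$meta, "MILK", "INFANT_ORAL")
  calls <- classify_pair_sharing(pairs, "Streptococcus", ds$table, ds$records,
                                 ds$taxonomy)
  swapped <- pairs
  swapped[, c("sample_a", "sample_b", "family_a", "family_b")] <-
    swapped[, c("sample_b", "sample_a", "family_b", "family_a")]
  calls_sw <- classify_pair_sharing(swapped, "Streptococcus", ds$table,
                                    ds$records, ds$taxonomy)
  expect_identical(calls$status, calls_sw$status)

  relabel <- setNames(c("z9", "z8", "z7", "z6"), c("a1", "a2", "b1", "c1"))
  tab2 <- ds$table; colnames(tab2) <- relabel[colnames(tab2)]
  rec2 <- ds$records; rec2$asv_id <- relabel[rec2$asv_id]
  tax2 <- ds$taxonomy; tax2$asv_id <- relabel[tax2$asv_id]
  calls2 <- classify_pair_sharing(pairs, "Streptococcus", asv_table(tab2),
                                  rec2, tax2)
  expect_identical(calls$status, calls2$status)
})

test_that("the exact 2x2 test matches closed forms and the stats reference", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1)$p, 1)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5)$p, 2 / choose(10, 5))
  expect_identical(fisher_exact_2x2(5, 0, 0, 5)$odds_ratio, Inf)
  expect_identical(fisher_exact_2x2(0, 5, 5, 0)$odds_ratio, 0)
  expect_true(is.na(fisher_exact_2x2(0, 0, 0, 0)$odds_ratio))
  expect_equal(fisher_exact_2x2(0, 0, 0, 0)$p, 1)

  set.seed(18)
  for (i in 1:50) {
    cells <- as.integer(rpois(4, 6))
    mine <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("sharing tests build the right tables and control the FDR family", {
  # forced design: all related pairs share, no unrelated pair does
  cfg <- sim_config(n_families = 14, p_share = 1, p_bg = 0, seed = 51)
  ds <- simulate_cohort(cfg)
  pairs <- enumerate_pairs(ds$meta, "MILK", "INFANT_ORAL")
  calls <- do.call(rbind, lapply(cfg$genera, classify_pair_sharing,
                                 pairs = pairs, table = ds$table,
                                 records = ds$records, taxonomy = ds$taxonomy))
  res <- sharing_tests(calls)
  expect_true(all(res$related_shared == res$related_total))
  expect_true(all(res$unrelated_shared == 0))
  expect_true(all(res$fdr < 0.05))
  expect_true(all(res$significance != ""))

  # equal sharing fractions give no signal
  eq <- fisher_exact_2x2(7, 7, 91, 91)
  expect_gte(eq$p, 0.5)

  # no sharing at all: p = 1 everywhere
  calls0 <- calls; calls0$status[calls0$status == "SHARED"] <- "PRESENT_NOT_SHARED"
  res0 <- sharing_tests(calls0)
  expect_true(all(res0$p == 1))
})

test_that("BH adjustment is a valid step-up within the family", {
  cfg <- sim_config(n_families = 8, seed = 53)
  ds <- simulate_cohort(cfg)
  pairs <- enumerate_pairs(ds$meta, "MILK", "INFANT_FAECES")
  calls <- do.call(rbind, lapply(cfg$genera, classify_pair_sharing,
                                 pairs = pairs, table = ds$table,
                                 records = ds$records, taxonomy = ds$taxonomy))
  res <- sharing_tests(calls)
  expect_true(all(res$fdr >= res$p - 1e-12))
  expect_true(all(res$fdr <= 1))
  ord <- order(res$p)
  expect_true(all(diff(res$fdr[ord]) >= -1e-12))
  expect_equal(res$fdr, p.adjust(res$p, "BH"))
})

test_that("the restricted denominator drops absent pairs from the table", {
  ds <- tiny_dataset()
  pairs <- enumerate_pairs(ds$meta, "MILK", "INFANT_ORAL")
  calls <- classify_pair_sharing(pairs, "Rothia", ds$table, ds$records,
                                 ds$taxonomy)
  all_mode <- sharing_tests(calls, denominator = "all")
  strict <- sharing_tests(calls, denominator = "present_both")
  expect_gt(all_mode$related_total + all_mode$unrelated_total,
            strict$related_total + strict$unrelated_total)
})

test_that("neighbour joining recovers additive metrics", {
  d4 <- matrix(c(0, 2, 4, 4,
                 2, 0, 4, 4,
                 4, 4, 0, 2,
                 4, 4, 2, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d4)
  coph <- as.matrix(ape::cophenetic.phylo(tr))
  expect_equal(coph[rownames(d4), colnames(d4)], d4, tolerance = 1e-9)
  # split AB|CD: internal edge 2, leaf edges 1
  expect_equal(sort(tr$edge.length), c(1, 1, 1, 1, 2), tolerance = 1e-9)

  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- nj_tree(d2)
  expect_equal(sum(t2$edge.length), 3)

  set.seed(19)
  for (n in 4:8) {
    dm <- random_additive_metric(n)
    trn <- nj_tree(dm)
    cc <- as.matrix(ape::cophenetic.phylo(trn))
    expect_equal(cc[rownames(dm), colnames(dm)], dm, tolerance = 1e-8)
  }

  bad <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(bad), "symmetric")
  expect_match(to_newick(tr), "^\\(.*\\);$")
})
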