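test_that("genus aggregation sums counts and closes abundances", {
  ds <- tiny_dataset()
  g <- genus_aggregate(ds$table, ds$taxonomy)
  # F01_MILK: Streptococcus 5, Rothia 3, Cutibacterium 0
  expect_identical(g$counts["F01_MILK", "Streptococcus"], 5L)
  expect_equal(g$abund["F01_MILK", "Streptococcus"], 5 / 8)
  expect_true(all(abs(rowSums(g$abund)[g$totals > 0] - 1) < 1e-9))

  # two ASVs of one genus sum within a sample
  expect_identical(g$counts["F02_MILK", "Streptococcus"], 4L)

  # all-unclassified table collapses to one column at abundance 1
  tab <- asv_table(matrix(c(3L, 7L), 1, 2,
                          dimnames = list("s1", c("x", "y"))))
  tax <- data.frame(asv_id = c("x", "y"), genus = "UNCLASSIFIED",
                    species = "UNCLASSIFIED")
  gu <- genus_aggregate(tab, tax)
  expect_identical(colnames(gu$abund), "OTHER_UNCLASSIFIED")
  expect_equal(unname(gu$abund[1, 1]), 1)

  # zero-read samples are flagged, not normalized
  tab0 <- asv_table(matrix(c(1L, 0L), 2, 1,
                           dimnames = list(c("s1", "s2"), "x")))
  g0 <- genus_aggregate(tab0, data.frame(asv_id = "x", genus = "A",
                                         species = "UNCLASSIFIED"))
  expect_identical(g0$zero_samples, "s2")
})

test_that("CLR transform matches the closed form and centres rows", {
  clr <- clr_transform(matrix(c(0.8, 0.2), 1, 2,
                              dimnames = list("s", c("a", "b"))),
                       pseudocount = 0)
  expect_equal(unname(clr[1, ]), c(log(2), -log(2)), tolerance = 1e-12)

  uni <- clr_transform(matrix(1 / 4, 2, 4,
                              dimnames = list(c("s1", "s2"), letters[1:4])),
                       pseudocount = 0)
  expect_true(all(abs(uni) < 1e-12))

  set.seed(2)
  x <- matrix(rexp(60), 10, 6, dimnames = list(paste0("s", 1:10), letters[1:6]))
  clr2 <- clr_transform(x / rowSums(x), pseudocount = 0)
  expect_lt(max(abs(rowSums(clr2))), 1e-9)

  withz <- matrix(c(0, 1, 2, 3), 2, 2, dimnames = list(c("s1", "s2"),
                                                       c("a", "b")))
  expect_error(clr_transform(withz, pseudocount = 0), "zero")
})

test_that("CLR is invariant to sample-wise count rescaling", {
  set.seed(3)
  x <- matrix(rpois(40, 20) + 1, 8, 5,
              dimnames = list(paste0("s", 1:8), letters[1:5]))
  scaled <- x * 7
  expect_equal(clr_transform(x, pseudocount = 0),
               clr_transform(scaled, pseudocount = 0), tolerance = 1e-12)
})

test_that("Aitchison distances are Euclidean on CLR rows and metric", {
  clr <- clr_transform(rbind(s1 = c(0.8, 0.2), s2 = c(0.2, 0.8)),
                       pseudocount = 0)
  d <- aitchison_distances(clr)
  expect_equal(d["s1", "s2"], 2 * sqrt(2) * log(2), tolerance = 1e-12)
  expect_equal(unname(diag(d)), c(0, 0))

  set.seed(4)
  x <- matrix(rexp(300), 100, 3)
  rownames(x) <- paste0("s", 1:100)
  dd <- aitchison_distances(clr_transform(x / rowSums(x), pseudocount = 0))
  for (k in 1:200) {
    ijk <- sample(100, 3)
    expect_lte(dd[ijk[1], ijk[3]],
               dd[ijk[1], ijk[2]] + dd[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("Aitchison distances agree with the community-ecology reference", {
  skip_if_not_installed("vegan")
  set.seed(9)
  counts <- matrix(rpois(60, 50) + 1, 6, 10,
                   dimnames = list(paste0("s", 1:6), paste0("g", 1:10)))
  mine <- aitchison_distances(clr_transform(counts, pseudocount = 0))
  ref <- as.matrix(vegan::vegdist(counts, method = "aitchison"))
  expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-8)
})

test_that("PCoA reproduces simple geometry and re-embeds Euclidean matrices", {
  d2 <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  p2 <- pcoa_ordination(d2)
  expect_equal(sort(unname(p2$coords[, 1])), c(-1, 1))
  expect_equal(p2$var_frac[1], 1)

  set.seed(6)
  x <- matrix(rexp(25 * 6), 25, 6, dimnames = list(paste0("s", 1:25), NULL))
  d <- aitchison_distances(clr_transform(x / rowSums(x), pseudocount = 0))
  p <- pcoa_ordination(d)
  expect_length(p$negative_eig, 0)
  emb <- as.matrix(dist(p$coords))
  expect_lt(max(abs(emb - d)), 1e-6)
})

test_that("PERMANOVA partitions variance and matches degenerate geometry", {
  # two tight groups: the group term explains everything
  pts <- rbind(matrix(0, 10, 2), matrix(1, 10, 2))
  rownames(pts) <- paste0("s", 1:20)
  d <- as.matrix(dist(pts))
  res <- permanova(d, data.frame(g = rep(c("A", "B"), each = 10)),
                   n_perm = 199, seed = 1)
  tab <- res$table
  expect_equal(tab$r2[tab$term == "g"], 1, tolerance = 1e-9)
  expect_equal(tab$p[tab$term == "g"], 1 / 200)
  expect_equal(sum(tab$r2[tab$term != "Total"]), 1, tolerance = 1e-9)
})

test_that("PERMANOVA agrees with the vegan reference on observed statistics", {
  skip_if_not_installed("vegan")
  set.seed(7)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("s", 1:20), NULL))
  d <- as.matrix(dist(x))
  fac <- data.frame(g = rep(c("A", "B", "C", "D"), 5),
                    h = sample(c("u", "v"), 20, replace = TRUE))
  mine <- permanova(d, fac, n_perm = 99, seed = 1)$table
  ref <- vegan::adonis2(as.dist(d) ~ g + h, data = fac, permutations = 99,
                        by = "terms")
  expect_equal(mine$SS[1:2], ref$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(mine$r2[1:2], ref$R2[1:2], tolerance = 1e-8)
  expect_equal(mine$pseudo_F[1:2], ref$F[1:2], tolerance = 1e-8)
})

test_that("exhaustive PERMANOVA p equals an independent enumeration at n = 6", {
  set.seed(8)
  x <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  d <- as.matrix(dist(x))
  groups <- c("A", "A", "A", "B", "B", "B")
  res <- permanova(d, data.frame(g = groups), exhaustive = TRUE)
  f_obs <- oracle_permanova_F(d, groups)
  perms <- oracle_perms(6)[-1, ]
  f_perm <- apply(perms, 1, function(p) oracle_permanova_F(d[p, p], groups))
  p_oracle <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + nrow(perms))
  expect_equal(res$table$pseudo_F[1], f_obs, tolerance = 1e-9)
  expect_equal(res$table$p[1], p_oracle)
})

test_that("single-level factors are skipped with a warning", {
  d <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
  dimnames(d) <- list(paste0("s", 1:5), paste0("s", 1:5))
  expect_warning(
    res <- permanova(d, data.frame(g = c("A", "A", "B", "B", "A"),
                                   k = rep("x", 5)), n_perm = 49, seed = 1),
    "single-level")
  expect_false("k" %in% res$table$term)
})

test_that("hierarchical clustering merges closest pairs first, order-invariantly", {
  d <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h <- hclust_order(d)
  expect_identical(sort(h$labels[-h$merge[1, ]]), c("A", "B"))

  # ultrametric input: cophenetic distances reproduce the input exactly
  um <- matrix(c(0, 2, 6, 6, 2, 0, 6, 6, 6, 6, 0, 4, 6, 6, 4, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  hu <- hclust_order(um, "average")
  coph <- as.matrix(cophenetic(hu))
  expect_equal(coph[rownames(um), colnames(um)], um, tolerance = 1e-12)

  perm <- c(3, 1, 4, 2)
  hp <- hclust_order(um[perm, perm], "average")
  expect_equal(as.matrix(cophenetic(hp))[rownames(um), colnames(um)], um,
               tolerance = 1e-12)
})

test_that("mock evaluation reports missing, unexpected and trace genera", {
  ref <- default_mock_reference()
  same <- evaluate_mock(ref, ref)
  expect_length(same$missing, 0)
  expect_length(same$unexpected, 0)
  expect_equal(same$aitchison_distance, 0, tolerance = 1e-9)

  obs <- ref[1:5] / sum(ref[1:5])   # three of eight genera dropped
  m <- evaluate_mock(obs, ref)
  expect_identical(sort(m$missing), sort(names(ref)[6:8]))

  obs2 <- c(ref * 0.9999, Bifidobacterium = 1e-4)
  obs2 <- obs2 / sum(obs2)
  m2 <- evaluate_mock(obs2, ref)
  expect_identical(m2$unexpected, "Bifidobacterium")
  expect_identical(m2$trace_unexpected, "Bifidobacterium")
})

test_that("core genera follow the prevalence threshold exactly", {
  ab <- matrix(0, 9, 2, dimnames = list(paste0("s", 1:9), c("g7", "g6")))
  ab[1:7, "g7"] <- 0.5; ab[1:6, "g6"] <- 0.5
  g <- structure(list(abund = ab, counts = ab, totals = rep(1, 9),
                      zero_samples = character(0)), class = "genus_table")
  expect_identical(core_genera(g, 0.7), "g7")     # 7/9 >= 0.7, 6/9 < 0.7
  expect_identical(core_genera(g, 1.0), character(0))
})

test_that("display filter keeps prevalent-and-abundant genera and pools the rest", {
  ab <- rbind(s1 = c(rare_one = 0.05, low = 0.01, dom = 0.16, ok = 0.05),
              s2 = c(rare_one = 0,    low = 0.01, dom = 0.01, ok = 0.03))
  ab <- cbind(ab, OTHER_UNCLASSIFIED = 1 - rowSums(ab))
  for (i in 3:10) {
    extra <- c(rare_one = 0, low = 0.01, dom = 0, ok = 0.04)
    ab <- rbind(ab, c(extra, OTHER_UNCLASSIFIED = 1 - sum(extra)))
    rownames(ab)[i] <- paste0("s", i)
  }
  g <- structure(list(abund = ab, counts = ab, totals = rep(1, nrow(ab)),
                      zero_samples = character(0)), class = "genus_table")
  f <- display_filter(g)
  expect_false("rare_one" %in% f$retained)   # 5% but in one sample only
  expect_false("low" %in% f$retained)        # never reaches 2%
  expect_identical(sort(f$retained), c("dom", "ok"))
  expect_identical(f$dominant, "dom")        # 16% in one sample
  expect_true(all(abs(rowSums(f$abund) - 1) < 1e-9))
})

test_that("per-genus CLR models recover planted method shifts under FDR control", {
  set.seed(12)
  n_per <- 30; n_genera <- 50; shifted <- paste0("g", 1:5)
  method <- rep(c("A", "B"), each = n_per)
  sample_id <- rep(sprintf("m%02d", 1:10), 6)
  clr <- matrix(rnorm(2 * n_per * n_genera, sd = 0.5), 2 * n_per, n_genera,
                dimnames = list(NULL, paste0("g", 1:n_genera)))
  clr <- clr + rnorm(10)[match(sample_id, sprintf("m%02d", 1:10))]
  clr[method == "B", shifted] <- clr[method == "B", shifted] + 1
  res <- clr_genus_models(clr, method, data.frame(sample = sample_id))
  hits <- res$genus[res$fdr < 0.05]
  expect_gte(length(intersect(hits, shifted)), 4)
  expect_lte(length(setdiff(hits, shifted)), 3)
  est <- res$estimate[match(shifted, res$genus)]
  expect_true(all(abs(est - 1) < 0.5))

  # null data: no discoveries
  clr0 <- matrix(rnorm(2 * n_per * 20, sd = 0.5), 2 * n_per, 20,
                 dimnames = list(NULL, paste0("n", 1:20)))
  res0 <- clr_genus_models(clr0, method)
  expect_identical(sum(res0$fdr < 0.05), 0L)
})

test_that("collinear fixed effects are reported by name", {
  clr <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("g1", "g2")))
  method <- rep(c("A", "B"), each = 5)
  expect_error(clr_genus_models(clr, method,
                                data.frame(dup = method)),
               "collinear")
})

test_that("group comparison tests behave canonically", {
  set.seed(13)
  # Kruskal-Wallis with two groups matches Mann-Whitney on tie-free data
  v <- rnorm(40); grp <- rep(c("A", "B"), 20)
  kw <- group_compare(v, grp, "KRUSKAL_WALLIS_DUNN")
  mw <- group_compare(v, grp, "MANN_WHITNEY")
  expect_equal(kw$p, mw$p, tolerance = 0.02)
  expect_identical(nrow(kw$posthoc), 1L)

  # perfectly monotone decreasing pairs give Spearman rho -1
  sp <- group_compare(10:1, (1:10)^2, "SPEARMAN")
  expect_equal(sp$statistic, -1)

  expect_error(group_compare(v, rep("A", 40), "MANN_WHITNEY"), "2")

  fish <- group_compare(rep(c("x", "y"), c(10, 10)),
                        rep(c("p", "q", "p", "q"), c(9, 1, 1, 9)), "FISHER")
  expect_lt(fish$p, 0.01)
})

test_that("Mann-Whitney holds its size on null data", {
  set.seed(14)
  rej <- mean(replicate(400, {
    v <- rnorm(30)
    group_compare(v, rep(c("A", "B"), 15), "MANN_WHITNEY")$p < 0.05
  }))
  expect_gt(rej, 0.01); expect_lt(rej, 0.10)
})
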