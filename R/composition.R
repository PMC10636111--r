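# Compositional analysis: genus aggregation, CLR, Aitchison distances, PCoA,
# PERMANOVA, clustering, mock evaluation, prevalence/abundance summaries,
# per-genus linear models and group-comparison tests.

#' Aggregate an ASV table to genus level
#'
#' Counts are summed per genus; ASVs without genus-level classification are
#' pooled into `OTHER_UNCLASSIFIED`. Relative abundances are closed either
#' over all retained reads (default) or over classified-genus reads only.
#' Samples with zero reads are flagged and their abundance rows left at zero
#' (they are excluded from downstream distance computations).
#'
#' @param table an [asv_table()].
#' @param taxonomy taxonomy data.frame covering every ASV in `table`.
#' @param closure `"all"` (close over all retained reads) or `"classified"`
#'   (drop unclassified reads from the denominator).
#' @return a list of class `genus_table`: `counts` (samples x genera integer
#'   matrix), `abund` (relative abundances, rows summing to 1), `totals`
#'   (per-sample denominators) and `zero_samples`.
#' @export
genus_aggregate <- function(table, taxonomy, closure = c("all", "classified")) {
  closure <- match.arg(closure)
  missing <- setdiff(colnames(table), taxonomy$asv_id)
  if (length(missing))
    stop("genus_aggregate: taxonomy missing for ASV(s): ",
         paste(head(missing, 5), collapse = ", "))
  genus <- taxonomy$genus[match(colnames(table), taxonomy$asv_id)]
  genus[is.na(genus) | genus == "UNCLASSIFIED"] <- "OTHER_UNCLASSIFIED"
  counts <- t(rowsum(t(unclass(table)), genus))
  if (closure == "classified" && "OTHER_UNCLASSIFIED" %in% colnames(counts))
    counts_for_closure <- counts[, colnames(counts) != "OTHER_UNCLASSIFIED",
                                 drop = FALSE]
  else counts_for_closure <- counts
  totals <- rowSums(counts_for_closure)
  zero <- rownames(counts)[totals == 0]
  abund <- counts_for_closure / ifelse(totals > 0, totals, 1)
  structure(list(counts = counts, abund = abund, totals = totals,
                 zero_samples = zero, closure = closure),
            class = "genus_table")
}

#' Centred log-ratio transform
#'
#' Maps each composition row to `log(x / geometric mean(x))`, so every row
#' sums to zero. When applied to a [genus_aggregate()] result, the
#' `pseudocount` is added to the genus counts before closure (standard
#' count-zero treatment); when applied to a plain abundance matrix,
#' zeros require a positive pseudocount (added to the raw values).
#'
#' @param g a `genus_table` or a numeric matrix of compositions (samples x
#'   parts).
#' @param pseudocount value added to counts (or abundances) to handle zeros.
#' @return matrix of CLR values with the same dimnames; zero-total samples
#'   are dropped.
#' @export
clr_transform <- function(g, pseudocount = 0.5) {
  if (inherits(g, "genus_table")) {
    x <- g$counts[!rownames(g$counts) %in% g$zero_samples, , drop = FALSE]
    x <- x + pseudocount
  } else {
    x <- as.matrix(g)
  }
  if (any(x == 0)) {
    if (pseudocount <= 0)
      stop("clr_transform: zero values present and pseudocount is 0")
    if (!inherits(g, "genus_table")) x <- x + pseudocount
  }
  if (any(x <= 0)) stop("clr_transform: values must be positive after pseudocount")
  lx <- log(x)
  lx - rowMeans(lx)
}

#' Aitchison distance matrix
#'
#' Euclidean distances between CLR-transformed rows; a proper metric on the
#' simplex, invariant to sample-wise rescaling of counts.
#'
#' @param clr matrix of CLR values (samples x parts).
#' @return symmetric labelled distance matrix.
#' @export
aitchison_distances <- function(clr) {
  if (!all(is.finite(clr))) stop("aitchison_distances: non-finite CLR values")
  as.matrix(dist(clr))
}

check_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  if (any(d < 0)) stop("distance matrix entries must be >= 0")
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  d
}

#' Principal coordinates analysis
#'
#' Classical (Gower) scaling of a distance matrix: axes are ordered by
#' decreasing eigenvalue and per-axis variance fractions are computed over the
#' positive eigenvalues. Negative eigenvalues are reported, not clipped; an
#' Aitchison matrix is always Euclidean-embeddable so none arise beyond
#' numerical noise.
#'
#' @param d symmetric labelled distance matrix.
#' @return list with `coords` (samples x axes), `eig` (all eigenvalues),
#'   `var_frac` (variance fraction per returned axis) and `negative_eig`
#'   (eigenvalues below -1e-9 * max(eig), if any).
#' @export
pcoa_ordination <- function(d) {
  d <- check_distance_matrix(d)
  n <- nrow(d)
  if (n < 2) stop("pcoa_ordination: need at least two samples")
  fit <- suppressWarnings(cmdscale(as.dist(d), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > 1e-9 * max(abs(eig))
  coords <- fit$points[, seq_len(min(ncol(fit$points), sum(pos))), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  rownames(coords) <- rownames(d)
  list(coords = coords, eig = eig,
       var_frac = eig[seq_len(ncol(coords))] / sum(eig[pos]),
       negative_eig = eig[eig < -1e-9 * max(abs(eig))])
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Permutational multivariate ANOVA on a distance matrix
#'
#' Partitions the Gower-centred inner-product matrix by sequential (type-I)
#' sums of squares in the given factor order, computes a pseudo-F per term,
#' and assesses significance by whole-row label permutation:
#' `p = (1 + #permuted F >= observed F) / (1 + n_perm)`. Deterministic under
#' `seed`; `exhaustive = TRUE` enumerates all `n!` permutations (small n).
#'
#' @param d symmetric labelled distance matrix.
#' @param factors data.frame (or named list) of factors, one value per sample
#'   of `d`, tested in the given order.
#' @param n_perm number of random permutations.
#' @param seed integer seed for the permutation stream.
#' @param exhaustive use all permutations instead of random draws.
#' @return list of class `permanova_result`: `table` (term, df, SS, r2,
#'   pseudo_F, p), `n_perm`, `seed`.
#' @export
permanova <- function(d, factors, n_perm = 999, seed = 1L, exhaustive = FALSE) {
  d <- check_distance_matrix(d)
  n <- nrow(d)
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  if (nrow(factors) != n)
    stop("permanova: factors must have one row per sample")
  keep <- vapply(factors, function(f) length(unique(f)) > 1, logical(1))
  if (any(!keep)) {
    warning("permanova: skipping single-level factor(s): ",
            paste(names(factors)[!keep], collapse = ", "))
    factors <- factors[, keep, drop = FALSE]
  }
  if (ncol(factors) == 0) stop("permanova: no usable factors")
  if (n_perm < 1) stop("permanova: n_perm must be >= 1")

  A <- d^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * C %*% A %*% C
  ss_total <- sum(diag(G))

  # cumulative hat matrices (intercept, then +term k)
  hats <- list(matrix(1 / n, n, n))
  ranks <- 1L
  X <- matrix(1, n, 1)
  for (k in seq_len(ncol(factors))) {
    X <- cbind(X, model.matrix(~ f, data.frame(f = factor(factors[[k]])))[, -1,
                                                                          drop = FALSE])
    q <- qr(X)
    ranks <- c(ranks, q$rank)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    hats[[k + 1]] <- Q %*% t(Q)
  }
  df <- diff(ranks)
  df_res <- n - ranks[length(ranks)]
  if (df_res < 1) stop("permanova: no residual degrees of freedom")

  stats_for <- function(Gp) {
    trs <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    ss <- diff(trs)
    ss_res <- sum(diag(Gp)) - trs[length(trs)]
    f <- (ss / df) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- stats_for(G)

  perms <- if (exhaustive) {
    m <- all_permutations(n)
    m[-1, , drop = FALSE]   # identity row is the observed ordering
  } else {
    with_seed(seed, t(vapply(seq_len(n_perm), function(i) sample.int(n),
                             integer(n))))
  }
  exceed <- numeric(length(df))
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    fp <- stats_for(G[p, p])$f
    exceed <- exceed + (fp >= obs$f - 1e-12)
  }
  pvals <- (1 + exceed) / (1 + nrow(perms))

  tab <- data.frame(
    term = c(names(factors), "Residual", "Total"),
    df = c(df, df_res, n - 1),
    SS = c(obs$ss, obs$ss_res, ss_total),
    r2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    pseudo_F = c(obs$f, NA, NA),
    p = c(pvals, NA, NA),
    stringsAsFactors = FALSE)
  structure(list(table = tab, n_perm = nrow(perms), seed = seed),
            class = "permanova_result")
}

#' Agglomerative clustering of a distance matrix
#'
#' Hierarchical clustering with the stated linkage (default average). Labels
#' are sorted before clustering so ties are broken by label order and the tree
#' topology does not depend on input row order.
#'
#' @param d symmetric labelled distance matrix.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return an `hclust` object (merge list, heights, leaf order, labels).
#' @export
hclust_order <- function(d, linkage = "average") {
  d <- check_distance_matrix(d)
  ord <- order(rownames(d))
  hclust(as.dist(d[ord, ord]), method = linkage)
}

#' Compare an observed mock community to its theoretical reference
#'
#' Reports detected, missing and unexpected genera (unexpected genera below
#' 0.02% relative abundance are flagged as trace), the per-genus log-ratio
#' bias over genera detected in both, and the Aitchison distance between the
#' observed and reference compositions (zeros replaced by `pseudo_frac`
#' before closure).
#'
#' @param observed named vector of genus counts or relative abundances.
#' @param reference a [mock_reference()] vector.
#' @param trace_threshold relative abundance below which an unexpected genus
#'   is called trace.
#' @param pseudo_frac replacement fraction for zero components in the
#'   distance computation.
#' @return list with `detected`, `missing`, `unexpected`, `trace_unexpected`,
#'   `log_ratio_bias` and `aitchison_distance`.
#' @export
evaluate_mock <- function(observed, reference, trace_threshold = 2e-4,
                          pseudo_frac = 1e-6) {
  reference <- mock_reference(reference)
  if (is.null(names(observed))) stop("evaluate_mock: observed must be named")
  obs <- observed[observed > 0]
  obs <- obs / sum(obs)
  expected <- names(reference)[reference > 0]
  detected <- intersect(expected, names(obs))
  missing <- setdiff(expected, names(obs))
  unexpected <- setdiff(names(obs), expected)
  trace <- unexpected[obs[unexpected] < trace_threshold]

  union_g <- union(expected, names(obs))
  o <- setNames(rep(pseudo_frac, length(union_g)), union_g)
  r <- setNames(rep(pseudo_frac, length(union_g)), union_g)
  o[names(obs)] <- obs
  r[names(reference)] <- reference
  o <- o / sum(o); r <- r / sum(r)
  clr2 <- clr_transform(rbind(observed = o, reference = r), pseudocount = 0)
  bias <- log(obs[detected] / reference[detected])
  list(detected = detected, missing = missing, unexpected = unexpected,
       trace_unexpected = trace, log_ratio_bias = bias,
       aitchison_distance = as.numeric(dist(clr2)))
}

#' Core genera by detection prevalence
#'
#' Genera detected (abundance > 0) in at least `prevalence_threshold` of the
#' selected samples.
#'
#' @param g a `genus_table`.
#' @param prevalence_threshold required prevalence in (0, 1].
#' @param samples optional sample-id subset.
#' @return character vector of core genus names.
#' @export
core_genera <- function(g, prevalence_threshold = 0.7, samples = NULL) {
  stopifnot(inherits(g, "genus_table"))
  if (prevalence_threshold <= 0 || prevalence_threshold > 1)
    stop("core_genera: threshold must be in (0, 1]")
  a <- g$abund
  if (!is.null(samples)) a <- a[rownames(a) %in% samples, , drop = FALSE]
  prev <- colMeans(a > 0)
  sort(names(prev)[prev >= prevalence_threshold])
}

#' Display filter for genus-level barplots
#'
#' A genus is retained iff it is present (abundance > 0) in at least
#' `min_samples` samples and reaches at least `min_abund` relative abundance
#' in at least one sample; all other genera (and unclassified reads) are
#' summed into `OTHER`. Genera reaching `dominant_abund` in at least one
#' sample are additionally flagged as dominant.
#'
#' @param g a `genus_table`.
#' @param min_samples minimum number of samples with the genus present.
#' @param min_abund minimum relative abundance reached in any sample.
#' @param dominant_abund dominance threshold.
#' @return list with `abund` (filtered matrix with an `OTHER` column),
#'   `retained` and `dominant` genus vectors.
#' @export
display_filter <- function(g, min_samples = 2, min_abund = 0.02,
                           dominant_abund = 0.15) {
  stopifnot(inherits(g, "genus_table"))
  a <- g$abund
  genera <- setdiff(colnames(a), "OTHER_UNCLASSIFIED")
  present_n <- colSums(a[, genera, drop = FALSE] > 0)
  max_ab <- apply(a[, genera, drop = FALSE], 2, max)
  retained <- genera[present_n >= min_samples & max_ab >= min_abund]
  other <- rowSums(a[, setdiff(colnames(a), retained), drop = FALSE])
  out <- cbind(a[, retained, drop = FALSE], OTHER = other)
  dominant <- retained[apply(a[, retained, drop = FALSE], 2, max) >= dominant_abund]
  list(abund = out, retained = sort(retained), dominant = sort(dominant))
}

#' Per-genus linear models on CLR abundances
#'
#' Fits ordinary least squares per genus with the CLR abundance as outcome
#' and the method factor plus covariate fixed effects (dummy coding) as
#' predictors; the method term is tested by a partial F test and p-values are
#' Benjamini-Hochberg adjusted across genera.
#'
#' @param clr CLR matrix (samples x genera).
#' @param outcome factor of interest (e.g. DNA isolation method), one value
#'   per row of `clr`.
#' @param covariates optional data.frame of fixed-effect factors (e.g. milk
#'   sample id).
#' @return data.frame with `genus`, `estimate` (first non-reference outcome
#'   level contrast), `p`, `fdr`.
#' @export
clr_genus_models <- function(clr, outcome, covariates = NULL) {
  df <- data.frame(.outcome = factor(outcome))
  if (!is.null(covariates))
    df <- cbind(df, as.data.frame(lapply(as.data.frame(covariates), factor)))
  full_form <- stats::as.formula(paste("~", paste(names(df), collapse = " + ")))
  X <- model.matrix(full_form, df)
  if (qr(X)$rank < ncol(X)) {
    drop_cols <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("clr_genus_models: rank-deficient design; collinear term(s): ",
         paste(drop_cols, collapse = ", "))
  }
  reduced <- if (ncol(df) > 1)
    stats::as.formula(paste("y ~", paste(names(df)[-1], collapse = " + ")))
  else y ~ 1
  res <- lapply(colnames(clr), function(g) {
    dat <- cbind(y = clr[, g], df)
    fit <- lm(stats::as.formula(paste("y ~", paste(names(df), collapse = " + "))),
              data = dat)
    fit0 <- lm(reduced, data = dat)
    a <- anova(fit0, fit)
    est <- stats::coef(fit)[grep("^\\.outcome", names(stats::coef(fit)))][1]
    data.frame(genus = g, estimate = unname(est), p = a$`Pr(>F)`[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p, method = "BH")
  out
}

dunn_posthoc <- function(values, grouping) {
  g <- factor(grouping)
  r <- rank(values)
  N <- length(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  S <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  mean_r <- tapply(r, g, mean)
  n <- table(g)
  pairs <- combn(levels(g), 2)
  z <- apply(pairs, 2, function(pr) {
    (mean_r[pr[1]] - mean_r[pr[2]]) /
      sqrt(S * (1 / n[pr[1]] + 1 / n[pr[2]]))
  })
  p <- 2 * pnorm(-abs(z))
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ], z = as.numeric(z),
             p = as.numeric(p), fdr = p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Group-comparison tests
#'
#' Dispatches the study's standard univariate tests: Kruskal-Wallis with
#' Dunn's rank-based post hoc (BH-adjusted over all pairwise comparisons
#' within the one Kruskal-Wallis family), Mann-Whitney U, Spearman rank
#' correlation (second argument is the paired continuous vector), or Fisher's
#' exact test on the cross-tabulation of two categorical vectors.
#'
#' @param values numeric (or categorical for FISHER) per-sample values.
#' @param grouping group labels, or the paired vector for SPEARMAN.
#' @param test one of `"KRUSKAL_WALLIS_DUNN"`, `"MANN_WHITNEY"`,
#'   `"SPEARMAN"`, `"FISHER"`.
#' @return list with `test`, `statistic`, `p`, `groups` and, for
#'   Kruskal-Wallis, a `posthoc` data.frame of Dunn z statistics.
#' @export
group_compare <- function(values, grouping,
                          test = c("KRUSKAL_WALLIS_DUNN", "MANN_WHITNEY",
                                   "SPEARMAN", "FISHER")) {
  test <- match.arg(test)
  if (test != "SPEARMAN") {
    tabn <- table(grouping)
    if (any(tabn == 0) || length(tabn) < 2)
      stop("group_compare: need >= 2 non-empty groups")
  }
  switch(test,
    KRUSKAL_WALLIS_DUNN = {
      kt <- kruskal.test(values, factor(grouping))
      list(test = test, statistic = unname(kt$statistic), p = kt$p.value,
           groups = levels(factor(grouping)),
           posthoc = dunn_posthoc(values, grouping))
    },
    MANN_WHITNEY = {
      if (length(unique(grouping)) != 2)
        stop("group_compare: MANN_WHITNEY needs exactly 2 groups")
      wt <- wilcox.test(values ~ factor(grouping), exact = FALSE)
      list(test = test, statistic = unname(wt$statistic), p = wt$p.value,
           groups = levels(factor(grouping)), posthoc = NULL)
    },
    SPEARMAN = {
      ok <- complete.cases(values, grouping)
      ct <- suppressWarnings(
        cor.test(values[ok], grouping[ok], method = "spearman", exact = FALSE))
      list(test = test, statistic = unname(ct$estimate), p = ct$p.value,
           groups = NULL, posthoc = NULL)
    },
    FISHER = {
      tab <- table(values, grouping)
      if (all(dim(tab) == 2)) {
        ft <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
        list(test = test, statistic = ft$odds_ratio, p = ft$p,
             groups = colnames(tab), posthoc = NULL)
      } else {
        ft <- stats::fisher.test(tab)
        list(test = test, statistic = NA_real_, p = ft$p.value,
             groups = colnames(tab), posthoc = NULL)
      }
    })
}
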