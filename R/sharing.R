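# Mother-infant ASV sharing: pair enumeration, candidate-genus selection,
# exact-identity sharing calls, Fisher exact tests with BH adjustment, and
# neighbour-joining trees from Hamming matrices.

#' Enumerate related and unrelated sample pairs for one body-site comparison
#'
#' Forms every (sample of `type_a`) x (sample of `type_b`) pair with distinct
#' sample ids; a pair is related iff both samples come from the same family.
#' With 14 families complete in both types this yields 14 related and 182
#' unrelated pairs; with one family missing `type_b`, 13 related and 169
#' unrelated.
#'
#' @param meta sample metadata (only rows with a family id are used).
#' @param type_a,type_b sample types to pair (e.g. `"MILK"`,
#'   `"INFANT_ORAL"`).
#' @param replicate_policy `"error"` (the pilot design has one sample per
#'   type per family) or `"collapse"` (collapse technical replicates first
#'   with [collapse_replicates()], then enumerate).
#' @return data.frame of class `pair_set` with columns `sample_a`,
#'   `sample_b`, `family_a`, `family_b`, `related`; attributes `comparison`,
#'   `n_related`, `n_unrelated`.
#' @export
enumerate_pairs <- function(meta, type_a, type_b,
                            replicate_policy = c("error", "collapse")) {
  replicate_policy <- match.arg(replicate_policy)
  for (tt in c(type_a, type_b))
    if (!tt %in% meta$sample_type)
      stop("enumerate_pairs: no samples of type ", tt)
  sub <- meta[!is.na(meta$family_id) & meta$sample_type %in% c(type_a, type_b), ]
  dup <- table(sub$family_id, sub$sample_type)
  if (any(dup > 1)) {
    if (replicate_policy == "error")
      stop("enumerate_pairs: family contributes >1 sample of a type: ",
           paste(rownames(dup)[apply(dup > 1, 1, any)], collapse = ", "),
           " (use replicate_policy = 'collapse' after collapse_replicates())")
    else
      stop("enumerate_pairs: collapse the table with collapse_replicates() ",
           "before enumerating pairs")
  }
  a <- sub[sub$sample_type == type_a, ]
  b <- sub[sub$sample_type == type_b, ]
  grid <- expand.grid(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)))
  pairs <- data.frame(
    sample_a = a$sample_id[grid$ia], sample_b = b$sample_id[grid$ib],
    family_a = a$family_id[grid$ia], family_b = b$family_id[grid$ib],
    stringsAsFactors = FALSE)
  pairs <- pairs[pairs$sample_a != pairs$sample_b, , drop = FALSE]
  pairs$related <- pairs$family_a == pairs$family_b
  rownames(pairs) <- NULL
  structure(pairs, class = c("pair_set", "data.frame"),
            comparison = paste0(type_a, "_vs_", type_b),
            n_related = sum(pairs$related),
            n_unrelated = sum(!pairs$related))
}

#' Collapse technical replicates by summing counts
#'
#' Sums the count rows of replicate samples of the same (family, sample type)
#' and keeps the first replicate's metadata row (replicate set to 1).
#'
#' @param table an [asv_table()].
#' @param meta sample metadata.
#' @return list with collapsed `table` and `meta`.
#' @export
collapse_replicates <- function(table, meta) {
  key <- ifelse(is.na(meta$family_id), meta$sample_id,
                paste(meta$family_id, meta$sample_type, sep = "/"))
  first <- !duplicated(key)
  summed <- rowsum(unclass(table)[meta$sample_id, , drop = FALSE], key)
  out_meta <- meta[first, , drop = FALSE]
  out <- summed[key[first], , drop = FALSE]
  rownames(out) <- out_meta$sample_id
  out_meta$replicate <- 1L
  list(table = asv_table(out), meta = out_meta)
}

genus_asvs <- function(genus, taxonomy) taxonomy$asv_id[taxonomy$genus == genus]

#' Select candidate genera for sharing analysis
#'
#' A genus qualifies iff it is detected (count >= 1) in both members of at
#' least `min_related_pairs` related pairs.
#'
#' @param table an [asv_table()].
#' @param taxonomy taxonomy data.frame.
#' @param pairs a [enumerate_pairs()] pair set.
#' @param min_related_pairs required number of related pairs with the genus
#'   in both members.
#' @return character vector of candidate genus names.
#' @export
select_candidate_genera <- function(table, taxonomy, pairs,
                                    min_related_pairs = 2) {
  rel <- pairs[pairs$related, , drop = FALSE]
  genera <- setdiff(sort(unique(taxonomy$genus)), "UNCLASSIFIED")
  ok <- vapply(genera, function(g) {
    asvs <- intersect(genus_asvs(g, taxonomy), colnames(table))
    if (!length(asvs)) return(FALSE)
    gc <- rowSums(table[, asvs, drop = FALSE])
    sum(gc[rel$sample_a] >= 1 & gc[rel$sample_b] >= 1) >= min_related_pairs
  }, logical(1))
  genera[ok]
}

#' Classify ASV sharing for sample pairs of one genus
#'
#' A pair is `SHARED` iff some ASV of the genus has an identical normalized
#' sequence with at least `min_count` reads in both samples (exact string
#' identity; no alignment is involved), `PRESENT_NOT_SHARED` iff the genus is
#' detected in both samples but no identical ASV exists, else
#' `ABSENT_IN_ONE_OR_BOTH`.
#'
#' @param pairs a [enumerate_pairs()] pair set.
#' @param genus genus name.
#' @param table an [asv_table()].
#' @param records ASV sequence data.frame.
#' @param taxonomy taxonomy data.frame.
#' @param min_count read threshold for detection (default 1).
#' @return data.frame of calls: pair columns plus `genus`, `status`,
#'   `shared_asv_ids` (comma-separated, possibly empty).
#' @export
classify_pair_sharing <- function(pairs, genus, table, records, taxonomy,
                                  min_count = 1) {
  asvs <- intersect(genus_asvs(genus, taxonomy), colnames(table))
  seqs <- setNames(records$sequence[match(asvs, records$asv_id)], asvs)
  sub <- table[, asvs, drop = FALSE]
  status <- character(nrow(pairs)); shared_ids <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    in_a <- asvs[sub[pairs$sample_a[i], ] >= min_count]
    in_b <- asvs[sub[pairs$sample_b[i], ] >= min_count]
    if (!length(in_a) || !length(in_b)) {
      status[i] <- "ABSENT_IN_ONE_OR_BOTH"; shared_ids[i] <- ""
    } else {
      shared_seq <- intersect(seqs[in_a], seqs[in_b])
      if (length(shared_seq)) {
        status[i] <- "SHARED"
        shared_ids[i] <- paste(sort(unique(
          c(in_a[seqs[in_a] %in% shared_seq],
            in_b[seqs[in_b] %in% shared_seq]))), collapse = ",")
      } else {
        status[i] <- "PRESENT_NOT_SHARED"; shared_ids[i] <- ""
      }
    }
  }
  cbind(as.data.frame(pairs), genus = genus, status = status,
        shared_asv_ids = shared_ids, stringsAsFactors = FALSE)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p by the probability-mass method: the sum of hypergeometric
#' probabilities (margins fixed) of all tables whose point probability is at
#' most the observed one (relative tolerance 1e-7 on the comparison). The
#' odds ratio is the sample odds ratio `a*d / (b*c)` with Inf/0 sentinels.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise
#'   (`[[a, b], [c, d]]`).
#' @return list with `p` and `odds_ratio` (NA for an all-zero table or 0/0).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("fisher_exact_2x2: cells must be non-negative integers")
  if (sum(cells) == 0) return(list(p = 1, odds_ratio = NA_real_))
  m1 <- a + b; m2 <- c + d; k <- a + c
  support <- max(0, k - m2):min(k, m1)
  probs <- dhyper(support, m1, m2, k)
  p_obs <- dhyper(a, m1, m2, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  num <- a * d; den <- b * c
  odds <- if (num == 0 && den == 0) NA_real_
          else if (den == 0) Inf
          else num / den
  list(p = p, odds_ratio = odds)
}

significance_stars <- function(fdr) {
  ifelse(is.na(fdr), "", ifelse(fdr < 0.001, "***",
    ifelse(fdr < 0.01, "**", ifelse(fdr < 0.05, "*", ""))))
}

#' Per-genus sharing tests over a pair-call table
#'
#' Builds, per genus, the 2x2 table of related/unrelated x shared/not-shared
#' pairs, computes the two-sided exact p and BH-adjusts across the genera of
#' the call family (one body-site comparison). By default the not-shared
#' margin pools `PRESENT_NOT_SHARED` and `ABSENT_IN_ONE_OR_BOTH` pairs
#' (percentages are over all pairs); `denominator = "present_both"` restricts
#' each genus' table to pairs with the genus detected in both members.
#'
#' @param calls row-bound [classify_pair_sharing()] results covering all
#'   pairs for every candidate genus of one comparison.
#' @param denominator `"all"` or `"present_both"`.
#' @return data.frame per genus: counts, status percentages, `odds_ratio`,
#'   `p`, `fdr`, `significance` stars (FDR < 0.05 / 0.01 / 0.001).
#' @export
sharing_tests <- function(calls, denominator = c("all", "present_both")) {
  denominator <- match.arg(denominator)
  res <- lapply(split(calls, calls$genus), function(df) {
    if (denominator == "present_both")
      df <- df[df$status != "ABSENT_IN_ONE_OR_BOTH", , drop = FALSE]
    if (nrow(df) == 0) {
      warning("sharing_tests: genus with zero usable pairs skipped")
      return(NULL)
    }
    rel <- df$related
    shared <- df$status == "SHARED"
    rs <- sum(rel & shared); rt <- sum(rel)
    us <- sum(!rel & shared); ut <- sum(!rel)
    ft <- fisher_exact_2x2(rs, rt - rs, us, ut - us)
    pct <- function(st, r) if (sum(df$related == r) == 0) NA_real_ else
      100 * mean(df$status[df$related == r] == st)
    data.frame(genus = df$genus[1],
               related_shared = rs, related_total = rt,
               unrelated_shared = us, unrelated_total = ut,
               pct_related_shared = pct("SHARED", TRUE),
               pct_related_present_not_shared = pct("PRESENT_NOT_SHARED", TRUE),
               pct_related_absent = pct("ABSENT_IN_ONE_OR_BOTH", TRUE),
               pct_unrelated_shared = pct("SHARED", FALSE),
               pct_unrelated_present_not_shared = pct("PRESENT_NOT_SHARED", FALSE),
               pct_unrelated_absent = pct("ABSENT_IN_ONE_OR_BOTH", FALSE),
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0)
    stop("sharing_tests: no genus with usable pairs")
  rownames(out) <- NULL
  out$fdr <- p.adjust(out$p, method = "BH")
  out$significance <- significance_stars(out$fdr)
  out
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Q-criterion neighbour joining (exactly recovers additive
#' metrics). Labels are sorted so agglomeration ties are broken by label
#' order; negative branch lengths are clamped to zero with a message.
#'
#' @param d symmetric labelled distance matrix (n >= 2).
#' @return an [ape::nj()] `phylo` object; serialize with [to_newick()].
#' @export
nj_tree <- function(d) {
  d <- check_distance_matrix(d)
  n <- nrow(d)
  if (n < 2) stop("nj_tree: need at least two taxa")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  if (n == 2) {
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 edge.length = rep(d[1, 2] / 2, 2),
                 tip.label = rownames(d), Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }
  tree <- ape::nj(as.dist(d))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message("nj_tree: clamped ", sum(neg), " negative branch length(s) to 0")
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Serialize a tree to Newick
#'
#' @param tree a `phylo` object.
#' @return single Newick string.
#' @export
to_newick <- function(tree) ape::write.tree(tree)
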