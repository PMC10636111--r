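# Fixture builders and independent oracles, all constructed in code.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# tiny hand-built dataset: 2 families x (milk, infant oral), one control.
# Sequences are 420 bp (inside the short-mode window); a1 and a2 differ at a
# single site (Hamming distance 1).
tiny_dataset <- function() {
  set.seed(4242)
  a1 <- random_seq(420)
  a2_chars <- strsplit(a1, "")[[1]]
  a2_chars[5] <- setdiff(c("A", "C", "G", "T"), a2_chars[5])[1]
  asvs <- c(a1 = a1, a2 = paste(a2_chars, collapse = ""),
            b1 = random_seq(420), c1 = random_seq(420))
  counts <- rbind(
    F01_MILK = c(5, 0, 3, 0), F01_INFANT_ORAL = c(3, 0, 0, 0),
    F02_MILK = c(0, 4, 2, 1), F02_INFANT_ORAL = c(0, 2, 1, 0),
    NEG_PS_1 = c(0, 0, 0, 2))
  colnames(counts) <- names(asvs)
  meta <- data.frame(
    sample_id = rownames(counts),
    family_id = c("F01", "F01", "F02", "F02", NA),
    sample_type = c("MILK", "INFANT_ORAL", "MILK", "INFANT_ORAL",
                    "NEG_ISOLATION"),
    isolation_method = "PS", sequencing_method = "SHORT_16S",
    replicate = 1L, dna_yield_ng = c(10, 20, 30, 40, 0),
    stringsAsFactors = FALSE)
  records <- data.frame(asv_id = names(asvs), sequence = unname(asvs),
                        length_bp = nchar(asvs), stringsAsFactors = FALSE)
  taxonomy <- data.frame(
    asv_id = names(asvs),
    genus = c("Streptococcus", "Streptococcus", "Rothia", "Cutibacterium"),
    species = "UNCLASSIFIED", stringsAsFactors = FALSE)
  list(table = asv_table(counts), meta = meta, records = records,
       taxonomy = taxonomy)
}

# metadata for n_a milk samples and n_b samples of another type, one family
# per index (family i contributes milk i and, if i <= n_b, the other sample)
pairing_meta <- function(n_a, n_b, type_b = "MATERNAL_FAECES") {
  fams <- sprintf("F%02d", seq_len(max(n_a, n_b)))
  rbind(
    data.frame(sample_id = paste0(fams[seq_len(n_a)], "_MILK"),
               family_id = fams[seq_len(n_a)], sample_type = "MILK",
               isolation_method = "PS", sequencing_method = "SHORT_16S",
               replicate = 1L, dna_yield_ng = 1, stringsAsFactors = FALSE),
    data.frame(sample_id = paste0(fams[seq_len(n_b)], "_", type_b),
               family_id = fams[seq_len(n_b)], sample_type = type_b,
               isolation_method = "PS", sequencing_method = "SHORT_16S",
               replicate = 1L, dna_yield_ng = 1, stringsAsFactors = FALSE))
}

# brute-force Hamming: independent character scan
brute_hamming <- function(seqs) {
  n <- length(seqs)
  d <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ci <- strsplit(seqs[[i]], "")[[1]]; cj <- strsplit(seqs[[j]], "")[[1]]
    d[i, j] <- sum(ci != cj)
  }
  d
}

# independent Gotoh DP computing only the optimal global alignment score
oracle_align_score <- function(s1, s2, match = 2, mismatch = -1,
                               gap_open = -5, gap_extend = -2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b); NEG <- -1e30
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- gap_open + (i - 2) * gap_extend
  for (j in 2:(m + 1)) Y[1, j] <- gap_open + (j - 2) * gap_extend
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (a[i - 1] == b[j - 1]) match else mismatch
    M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
    X[i, j] <- max(M[i - 1, j] + gap_open, X[i - 1, j] + gap_extend,
                   Y[i - 1, j] + gap_open)
    Y[i, j] <- max(M[i, j - 1] + gap_open, Y[i, j - 1] + gap_extend,
                   X[i, j - 1] + gap_open)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# score realized by a gapped sequence pair under the same affine convention
realized_align_score <- function(g1, g2, match = 2, mismatch = -1,
                                 gap_open = -5, gap_extend = -2) {
  c1 <- strsplit(g1, "")[[1]]; c2 <- strsplit(g2, "")[[1]]
  stopifnot(length(c1) == length(c2))
  score <- 0; in_gap1 <- FALSE; in_gap2 <- FALSE
  for (k in seq_along(c1)) {
    if (c1[k] == "-" || c2[k] == "-") {
      if (c1[k] == "-") {
        score <- score + if (in_gap1) gap_extend else gap_open
        in_gap1 <- TRUE; in_gap2 <- FALSE
      } else {
        score <- score + if (in_gap2) gap_extend else gap_open
        in_gap2 <- TRUE; in_gap1 <- FALSE
      }
    } else {
      score <- score + if (c1[k] == c2[k]) 2 else -1
      in_gap1 <- FALSE; in_gap2 <- FALSE
    }
  }
  score
}

# exhaustive hypergeometric p-value oracle built from binomial coefficients
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  xs <- max(0, k - m2):min(k, m1)
  probs <- choose(m1, xs) * choose(m2, k - xs) / choose(m1 + m2, k)
  p_obs <- probs[xs == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# one-factor PERMANOVA pseudo-F via the Huygens within-group identity
# (independent of the projection-matrix implementation)
oracle_permanova_F <- function(d, groups) {
  n <- nrow(d)
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  ss_between <- ss_total - ss_within
  df1 <- length(unique(groups)) - 1
  df2 <- n - length(unique(groups))
  (ss_between / df1) / (ss_within / df2)
}

# all permutations of 1..n (oracle-side enumeration)
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# additive tree metric from a random topology with positive branch lengths
random_additive_metric <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, br = function(k) runif(k, 0.5, 3))
  as.matrix(ape::cophenetic.phylo(tree))
}
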