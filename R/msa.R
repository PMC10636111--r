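# Progressive multiple sequence alignment (ClustalW-style): affine-gap
# pairwise global alignments give identity distances, an average-linkage
# guide tree orders the merges, and groups are combined by profile-profile
# alignment with the same Gotoh kernel.

one_hot_profile <- function(gapped) {
  rows <- c("A", "C", "G", "T", "-")
  m <- do.call(rbind, strsplit(gapped, ""))
  prof <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    vapply(rows, function(ch) mean(col == ch), numeric(1))
  }, numeric(5))
  rownames(prof) <- rows
  prof
}

default_msa_params <- function()
  list(match = 2, mismatch = -1, gap_open = -5, gap_extend = -2)

apply_path <- function(group1, group2, path) {
  # path codes: 0 both, 1 = column from group1 (gap into group2), 2 = reverse
  expand <- function(seqs, take_code) {
    chars <- strsplit(seqs, "")
    out <- lapply(chars, function(ch) {
      res <- character(length(path)); k <- 0
      for (i in seq_along(path)) {
        if (path[i] == 0 || path[i] == take_code) { k <- k + 1; res[i] <- ch[k] }
        else res[i] <- "-"
      }
      paste(res, collapse = "")
    })
    unlist(out)
  }
  c(expand(group1, 1L), expand(group2, 2L))
}

#' Global pairwise alignment with affine gap costs
#'
#' Needleman-Wunsch-Gotoh alignment of two DNA sequences; ties in the
#' traceback prefer the diagonal, then a gap in the second sequence.
#'
#' @param seq1,seq2 DNA strings over A, C, G, T.
#' @param params scoring list (`match`, `mismatch`, `gap_open`,
#'   `gap_extend`); `gap_open` is the cost of the first gap column,
#'   `gap_extend` of each further column.
#' @return list with gapped strings `a1`, `a2` and the fraction `identity`
#'   of alignment columns with identical residues.
#' @export
align_pair <- function(seq1, seq2, params = default_msa_params()) {
  if (!nzchar(seq1) || !nzchar(seq2)) stop("align_pair: empty sequence")
  path <- .align_profiles(one_hot_profile(seq1), one_hot_profile(seq2),
                          params$match, params$mismatch,
                          params$gap_open, params$gap_extend)
  al <- apply_path(seq1, seq2, path)
  c1 <- strsplit(al[1], "")[[1]]; c2 <- strsplit(al[2], "")[[1]]
  list(a1 = al[1], a2 = al[2], identity = mean(c1 == c2 & c1 != "-"))
}

#' Progressive multiple sequence alignment
#'
#' All-pairs global alignments (affine gaps) give distances
#' `1 - identity`; an average-linkage guide tree built from them fixes the
#' merge order, and clusters are merged by aligning their frequency profiles
#' with the same Gotoh kernel. Deterministic for fixed parameters and input
#' order (guide-tree ties resolve by input order, traceback ties prefer the
#' diagonal and then a gap in the later-merged group).
#'
#' @param sequences named character vector of >= 2 DNA sequences.
#' @param params scoring parameters, see [align_pair()].
#' @return object of class `msa_alignment`: list with `ids` and `seqs`
#'   (named, equal-length gapped strings; degapping row i reproduces the
#'   input sequence of id i).
#' @export
progressive_msa <- function(sequences, params = default_msa_params()) {
  n <- length(sequences)
  if (n < 2) stop("progressive_msa: need >= 2 sequences")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_len(n))
  if (any(!nzchar(sequences))) stop("progressive_msa: empty sequence")

  if (n == 2) {
    al <- align_pair(sequences[1], sequences[2], params)
    return(structure(list(ids = names(sequences),
                          seqs = setNames(c(al$a1, al$a2), names(sequences))),
                     class = "msa_alignment"))
  }

  d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    al <- align_pair(sequences[i], sequences[j], params)
    d[i, j] <- d[j, i] <- 1 - al$identity
  }
  guide <- hclust(as.dist(d), method = "average")

  clusters <- lapply(seq_len(n), function(i) sequences[i])
  for (step in seq_len(nrow(guide$merge))) {
    m <- guide$merge[step, ]
    pick <- function(x) if (x < 0) clusters[[-x]] else clusters[[n + x]]
    g1 <- pick(m[1]); g2 <- pick(m[2])
    path <- .align_profiles(one_hot_profile(g1), one_hot_profile(g2),
                            params$match, params$mismatch,
                            params$gap_open, params$gap_extend)
    merged <- apply_path(g1, g2, path)
    names(merged) <- c(names(g1), names(g2))
    clusters[[n + step]] <- merged
  }
  final <- clusters[[n + nrow(guide$merge)]]
  final <- final[names(sequences)]   # restore input order
  structure(list(ids = names(final), seqs = final), class = "msa_alignment")
}

#' Hamming distance matrix from an alignment
#'
#' Counts, for each sequence pair, the alignment columns where the rows
#' differ; a gap versus a base counts as a difference, gap versus gap as
#' equal. Zero distance holds iff the gapped rows are identical.
#'
#' @param a an `msa_alignment` (or named character vector of equal-length
#'   gapped strings).
#' @return symmetric integer distance matrix labelled by sequence id.
#' @export
hamming_matrix <- function(a) {
  seqs <- if (inherits(a, "msa_alignment")) a$seqs else a
  if (length(unique(nchar(seqs))) != 1)
    stop("hamming_matrix: rows must have equal length")
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- length(seqs)
  d <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}

#' Write an alignment to aligned FASTA
#'
#' @param a an `msa_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(a, path) {
  writeLines(as.vector(rbind(paste0(">", a$ids), a$seqs[a$ids])), path)
  invisible(path)
}
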