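#' Construct a validated ASV count table
#'
#' The central container of the package: a non-negative integer matrix of read
#' counts with samples as rows and ASVs as columns. Row and column names must
#' be unique and non-empty.
#'
#' @param counts numeric matrix (samples x ASVs) of non-negative integers with
#'   unique `rownames` (sample ids) and `colnames` (ASV ids).
#' @return an integer matrix of class `asv_table`.
#' @export
asv_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("asv_table: counts must have sample rownames and ASV colnames")
  if (anyDuplicated(rownames(counts)))
    stop("asv_table: duplicated sample id(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("asv_table: duplicated ASV id(s): ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("asv_table: counts must be numeric and complete")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("asv_table: counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  class(counts) <- c("asv_table", class(counts))
  counts
}

#' Read an ASV count table from TSV
#'
#' Expects a tab-separated file with a header row of ASV ids and sample ids in
#' the first column. Order is preserved from the file.
#'
#' @param path file path.
#' @return an [asv_table()].
#' @export
read_asv_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character", sep = "\t")
  if (ncol(df) < 1) stop("read_asv_table: no columns in ", path)
  sample_ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "numeric")
  if (anyNA(m)) stop("read_asv_table: non-numeric count cell in ", path)
  rownames(m) <- sample_ids
  asv_table(m)
}

#' Write an ASV count table to TSV
#'
#' @param table an [asv_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

normalize_sequence <- function(seq, mask_ambiguous = FALSE, id = "?") {
  s <- chartr("u", "t", tolower(seq))
  s <- toupper(s)
  bad <- gsub("[ACGT]", "", s)
  if (nzchar(bad)) {
    if (mask_ambiguous) {
      s <- gsub("[^ACGT]", "N", s)
    } else {
      stop("sequence ", id, " contains non-ACGT character(s): ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
    }
  }
  s
}

#' Read ASV sequences from FASTA
#'
#' Sequences are normalized to uppercase DNA with U mapped to T. Any other
#' character (including IUPAC ambiguity codes) is rejected unless
#' `mask_ambiguous = TRUE`, in which case it is masked to N; identity-based
#' sharing calls require an unambiguous alphabet. The ASV id is the first
#' whitespace-delimited token of the header.
#'
#' @param path FASTA file path.
#' @param mask_ambiguous mask non-ACGT characters to N instead of erroring.
#' @return data.frame with columns `asv_id`, `sequence`, `length_bp`.
#' @export
read_fasta <- function(path, mask_ambiguous = FALSE) {
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("read_fasta: duplicate ASV id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("read_fasta: empty sequence for id(s): ",
         paste(ids[empty], collapse = ", "))
  seqs <- mapply(normalize_sequence, seqs, id = ids,
                 MoreArgs = list(mask_ambiguous = mask_ambiguous),
                 USE.NAMES = FALSE)
  data.frame(asv_id = ids, sequence = seqs, length_bp = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write ASV sequences to FASTA
#'
#' @param records data.frame with columns `asv_id` and `sequence`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(setNames(records$sequence, records$asv_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Columns: `sample_id`, `family_id`, `sample_type`, `isolation_method`,
#' `sequencing_method`, `replicate`, `dna_yield_ng`. Empty `family_id` is
#' recorded as `NA` (controls and mocks); an empty `dna_yield_ng` field is a
#' missing measurement (`NA`), distinct from a below-detection yield of 0.
#'
#' @param path TSV file path.
#' @return data.frame of per-sample metadata.
#' @export
read_sample_meta <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character", sep = "\t")
  needed <- c("sample_id", "family_id", "sample_type", "isolation_method",
              "sequencing_method", "replicate", "dna_yield_ng")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("read_sample_meta: missing column(s): ",
                         paste(miss, collapse = ", "))
  df$family_id[!nzchar(df$family_id)] <- NA_character_
  df$replicate <- as.integer(df$replicate)
  df$dna_yield_ng <- suppressWarnings(
    ifelse(nzchar(df$dna_yield_ng), as.numeric(df$dna_yield_ng), NA_real_))
  validate_sample_meta(df)
  df
}

validate_sample_meta <- function(meta) {
  if (anyDuplicated(meta$sample_id))
    stop("sample metadata: duplicated sample_id(s): ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  bad_type <- setdiff(meta$sample_type, SAMPLE_TYPES)
  if (length(bad_type)) stop("sample metadata: unknown sample_type: ",
                             paste(bad_type, collapse = ", "))
  bad_m <- setdiff(meta$isolation_method, ISOLATION_METHODS)
  if (length(bad_m)) stop("sample metadata: unknown isolation_method: ",
                          paste(bad_m, collapse = ", "))
  ctrl <- meta$sample_type %in% c("NEG_ISOLATION", "NEG_LIBPREP", "MOCK")
  if (any(ctrl & !is.na(meta$family_id)))
    stop("sample metadata: control/mock samples must have empty family_id: ",
         paste(meta$sample_id[ctrl & !is.na(meta$family_id)], collapse = ", "))
  invisible(meta)
}

#' Write sample metadata to TSV
#'
#' @param meta metadata data.frame as returned by [read_sample_meta()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(meta, path) {
  out <- meta
  out$family_id[is.na(out$family_id)] <- ""
  out$dna_yield_ng <- ifelse(is.na(out$dna_yield_ng), "", as.character(out$dna_yield_ng))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ASV taxonomy table from TSV
#'
#' Columns `asv_id`, `genus`, `species`; empty classifications are recorded as
#' `"UNCLASSIFIED"`.
#'
#' @param path TSV file path.
#' @return data.frame with columns `asv_id`, `genus`, `species`.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character", sep = "\t")
  miss <- setdiff(c("asv_id", "genus", "species"), names(df))
  if (length(miss)) stop("read_taxonomy: missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$asv_id))
    stop("read_taxonomy: duplicated asv_id(s)")
  df$genus[!nzchar(df$genus)] <- "UNCLASSIFIED"
  df$species[!nzchar(df$species)] <- "UNCLASSIFIED"
  df
}

#' Read a theoretical mock-community reference from TSV
#'
#' Columns `genus` and `expected_fraction`; fractions must sum to 1.
#'
#' @param path TSV file path.
#' @return named numeric vector of expected relative abundances.
#' @export
read_mock_reference <- function(path) {
  df <- read.delim(path, sep = "\t")
  ref <- setNames(as.numeric(df$expected_fraction), df$genus)
  mock_reference(ref)
}

#' Construct a mock-community reference
#'
#' @param fractions named numeric vector of expected per-genus relative
#'   abundances, summing to 1 (tolerance 1e-9).
#' @return the validated named vector.
#' @export
mock_reference <- function(fractions) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("mock_reference: fractions must be named by genus")
  if (any(fractions < 0)) stop("mock_reference: negative fraction")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("mock_reference: fractions must sum to 1 (got ", sum(fractions), ")")
  fractions
}

#' Cross-validate an ASV dataset
#'
#' Checks that every sample in the count table has metadata, every ASV has a
#' sequence and a taxonomy row, and that all sequence lengths fall inside the
#' active amplicon length window (400-431 bp for short-read 16S;
#' 1900-3000 bp for long-read 16S-ITS-23S). Findings are reported, never
#' silently dropped.
#'
#' @param table an [asv_table()].
#' @param meta sample metadata data.frame.
#' @param records ASV sequence data.frame (see [read_fasta()]).
#' @param taxonomy taxonomy data.frame (see [read_taxonomy()]).
#' @param mode amplicon mode, `"short"` or `"long"`.
#' @param strict if TRUE, any finding raises an error.
#' @return data.frame of findings with columns `kind`, `id`, `detail`;
#'   zero rows when the dataset is fully consistent.
#' @export
validate_dataset <- function(table, meta, records, taxonomy,
                             mode = c("short", "long"), strict = FALSE) {
  mode <- match.arg(mode)
  win <- LENGTH_WINDOWS[[mode]]
  findings <- list()
  add <- function(kind, id, detail)
    findings[[length(findings) + 1]] <<- data.frame(
      kind = kind, id = id, detail = detail, stringsAsFactors = FALSE)

  for (s in setdiff(rownames(table), meta$sample_id))
    add("sample_without_metadata", s, "sample in table but not in metadata")
  for (s in setdiff(meta$sample_id, rownames(table)))
    add("metadata_without_sample", s, "metadata row without table sample")
  for (a in setdiff(colnames(table), records$asv_id))
    add("asv_without_sequence", a, "ASV in table but not in FASTA")
  for (a in setdiff(colnames(table), taxonomy$asv_id))
    add("asv_without_taxonomy", a, "ASV in table but not in taxonomy")

  known <- records[records$asv_id %in% colnames(table), , drop = FALSE]
  out <- known$length_bp < win[1] | known$length_bp > win[2]
  for (i in which(out))
    add("asv_length_out_of_window", known$asv_id[i],
        sprintf("length %d bp outside %d-%d bp window (%s mode)",
                known$length_bp[i], win[1], win[2], mode))
  bad_len <- nchar(known$sequence) != known$length_bp
  for (i in which(bad_len))
    add("asv_length_mismatch", known$asv_id[i],
        "length_bp does not equal sequence length")

  report <- if (length(findings)) do.call(rbind, findings) else
    data.frame(kind = character(), id = character(), detail = character(),
               stringsAsFactors = FALSE)
  if (strict && nrow(report))
    stop("validate_dataset: ", nrow(report), " finding(s); first: ",
         report$kind[1], " [", report$id[1], "]")
  report
}

#' Reconstruct replicate values from a published median and range
#'
#' Published per-kit summaries report `median (min-max)` over 1-3 replicates.
#' The individual replicate values are recovered as: n=1 the median itself;
#' n=2 the two range endpoints (the published median must then be their
#' midpoint, checked to 0.5 to allow integer rounding, otherwise a warning is
#' raised); n=3 the endpoints plus the median. The midpoint rule for n=2 is a
#' reconstruction convention, not information printed in the source tables.
#'
#' @param median published median.
#' @param lo,hi published range endpoints.
#' @param n number of replicates (1, 2 or 3).
#' @return numeric vector of length `n` (sorted).
#' @export
reconstruct_replicate_values <- function(median, lo, hi, n) {
  if (!n %in% 1:3) stop("reconstruct_replicate_values: n must be 1, 2 or 3")
  if (lo > median || median > hi)
    stop("reconstruct_replicate_values: need lo <= median <= hi")
  if (n == 1) {
    median
  } else if (n == 2) {
    if (abs((lo + hi) / 2 - median) > 0.5)
      warning(sprintf(
        "reconstruct_replicate_values: midpoint of range (%.1f) inconsistent with median %.1f",
        (lo + hi) / 2, median))
    c(lo, hi)
  } else {
    c(lo, median, hi)
  }
}
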