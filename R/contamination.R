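# Negative-control-based contamination detection and accounting. An ASV
# detected in both a biological sample and a corresponding negative control is
# a potential contaminant; nothing is filtered, only quantified.

#' Matched negative controls for a sample
#'
#' Default policy: all isolation negative controls processed with the same
#' isolation method, plus (optionally) all library-preparation controls.
#'
#' @param sample_id biological sample id.
#' @param meta sample metadata data.frame.
#' @param class `"isolation"`, `"libprep"` or `"both"`.
#' @return character vector of control sample ids.
#' @export
matched_controls <- function(sample_id, meta, class = c("both", "isolation",
                                                        "libprep")) {
  class <- match.arg(class)
  row <- meta[meta$sample_id == sample_id, , drop = FALSE]
  if (nrow(row) != 1) stop("matched_controls: unknown sample ", sample_id)
  iso <- meta$sample_id[meta$sample_type == "NEG_ISOLATION" &
                          meta$isolation_method == row$isolation_method]
  lib <- meta$sample_id[meta$sample_type == "NEG_LIBPREP"]
  switch(class, isolation = iso, libprep = lib, both = c(iso, lib))
}

#' Detect potential contaminant ASVs in a sample
#'
#' Returns the ASVs with at least `min_count` reads in the sample and at
#' least `min_count` reads in any matched negative control. Adding reads to a
#' control can only grow this set.
#'
#' @param table an [asv_table()].
#' @param sample_id biological sample id.
#' @param control_ids matched negative-control sample ids (>= 1 required).
#' @param min_count detection threshold in both sample and control.
#' @return character vector of contaminant ASV ids.
#' @export
detect_contaminants <- function(table, sample_id, control_ids, min_count = 1) {
  if (length(control_ids) < 1)
    stop("detect_contaminants: no matched negative control for sample ",
         sample_id)
  missing <- setdiff(c(sample_id, control_ids), rownames(table))
  if (length(missing))
    stop("detect_contaminants: sample(s) not in table: ",
         paste(missing, collapse = ", "))
  in_sample <- table[sample_id, ] >= min_count
  in_ctrl <- if (length(control_ids) == 1) table[control_ids, ] >= min_count
             else apply(table[control_ids, , drop = FALSE] >= min_count, 2, any)
  colnames(table)[in_sample & in_ctrl]
}

#' Contaminated read fraction of a sample
#'
#' @param table an [asv_table()].
#' @param sample_id biological sample id.
#' @param contaminants contaminant ASV id set (subset of table ASVs).
#' @return list with `fraction` (NA for a zero-read sample),
#'   `contaminated_reads` and `total_reads`.
#' @export
contamination_fraction <- function(table, sample_id, contaminants) {
  bad <- setdiff(contaminants, colnames(table))
  if (length(bad))
    stop("contamination_fraction: unknown ASV id(s): ",
         paste(bad, collapse = ", "))
  total <- sum(table[sample_id, ])
  contam <- sum(table[sample_id, contaminants])
  if (total == 0) {
    warning("contamination_fraction: sample ", sample_id,
            " has zero reads; fraction is missing")
    return(list(fraction = NA_real_, contaminated_reads = 0L, total_reads = 0L))
  }
  list(fraction = contam / total, contaminated_reads = contam,
       total_reads = total)
}

#' Per-sample contamination report
#'
#' Computes the contaminant ASV set and contaminated read fraction for every
#' biological sample against its matched controls (default policy: same-kit
#' isolation controls pooled with all library-preparation controls).
#'
#' @param table an [asv_table()].
#' @param meta sample metadata.
#' @param class control-matching class passed to [matched_controls()].
#' @param min_count detection threshold.
#' @return data.frame with one row per biological sample: `sample_id`,
#'   `isolation_method`, `n_contaminant_asvs`, `contaminated_reads`,
#'   `total_reads`, `fraction`, `matched_controls`.
#' @export
contamination_report <- function(table, meta, class = "both", min_count = 1) {
  bio <- meta[meta$sample_type %in% c("MILK", "INFANT_ORAL", "INFANT_FAECES",
                                      "MATERNAL_FAECES"), , drop = FALSE]
  rows <- lapply(bio$sample_id, function(sid) {
    ctrls <- matched_controls(sid, meta, class)
    ctrls <- intersect(ctrls, rownames(table))
    contam <- detect_contaminants(table, sid, ctrls, min_count)
    fr <- suppressWarnings(contamination_fraction(table, sid, contam))
    data.frame(sample_id = sid,
               isolation_method = bio$isolation_method[bio$sample_id == sid],
               n_contaminant_asvs = length(contam),
               contaminated_reads = fr$contaminated_reads,
               total_reads = fr$total_reads, fraction = fr$fraction,
               matched_controls = paste(ctrls, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Attribute contamination to isolation versus library preparation
#'
#' Computes each biological sample's contaminated read fraction separately
#' against the isolation-control class and the library-preparation-control
#' class, and summarises the min-max range per isolation method and source.
#'
#' @param table an [asv_table()].
#' @param meta sample metadata.
#' @param min_count detection threshold.
#' @return list with `per_sample` (sample_id, method, isolation_fraction,
#'   libprep_fraction) and `ranges` (method x source min/max).
#' @export
attribute_source <- function(table, meta, min_count = 1) {
  have_iso <- any(meta$sample_type == "NEG_ISOLATION")
  have_lib <- any(meta$sample_type == "NEG_LIBPREP")
  if (!have_iso && !have_lib)
    stop("attribute_source: no negative controls in metadata")
  bio <- meta[meta$sample_type %in% c("MILK", "INFANT_ORAL", "INFANT_FAECES",
                                      "MATERNAL_FAECES"), , drop = FALSE]
  frac_for <- function(sid, class, have) {
    if (!have) return(NA_real_)
    ctrls <- matched_controls(sid, meta, class)
    if (!length(ctrls)) return(NA_real_)
    contam <- detect_contaminants(table, sid, ctrls, min_count)
    suppressWarnings(contamination_fraction(table, sid, contam))$fraction
  }
  if (!have_iso) warning("attribute_source: no isolation controls; ",
                         "isolation-attributed column is missing")
  if (!have_lib) warning("attribute_source: no library-preparation controls; ",
                         "libprep-attributed column is missing")
  per_sample <- do.call(rbind, lapply(bio$sample_id, function(sid)
    data.frame(sample_id = sid,
               isolation_method = bio$isolation_method[bio$sample_id == sid],
               isolation_fraction = frac_for(sid, "isolation", have_iso),
               libprep_fraction = frac_for(sid, "libprep", have_lib),
               stringsAsFactors = FALSE)))
  rng <- function(x) if (all(is.na(x))) c(NA_real_, NA_real_)
                     else range(x, na.rm = TRUE)
  ranges <- do.call(rbind, lapply(split(per_sample,
                                        per_sample$isolation_method),
                                  function(df) {
    ri <- rng(df$isolation_fraction); rl <- rng(df$libprep_fraction)
    data.frame(isolation_method = df$isolation_method[1],
               isolation_min = ri[1], isolation_max = ri[2],
               libprep_min = rl[1], libprep_max = rl[2],
               stringsAsFactors = FALSE)
  }))
  rownames(ranges) <- NULL
  list(per_sample = per_sample, ranges = ranges)
}

#' Correlation between DNA yield and contamination
#'
#' Spearman rank correlation over samples with both a yield measurement and a
#' defined contamination fraction; incomplete pairs are dropped and counted.
#'
#' @param dna_yields named (by sample id) numeric vector of DNA yields (ng).
#' @param fractions named numeric vector of contaminated read fractions.
#' @return list with `rho`, `p`, `n_used`, `n_dropped`; `rho` is missing
#'   (NA, with a warning) when either vector is constant over complete pairs.
#' @export
yield_correlation <- function(dna_yields, fractions) {
  common <- intersect(names(dna_yields), names(fractions))
  x <- dna_yields[common]; y <- fractions[common]
  ok <- complete.cases(x, y)
  n_dropped <- length(common) - sum(ok)
  if (sum(ok) < 3)
    stop("yield_correlation: need >= 3 complete pairs, got ", sum(ok))
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("yield_correlation: constant vector; rho is undefined (missing)")
    return(list(rho = NA_real_, p = NA_real_, n_used = sum(ok),
                n_dropped = n_dropped))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n_used = sum(ok),
       n_dropped = n_dropped)
}
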