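# End-to-end orchestration: stage sequencing, configuration validation,
# run manifest, atomic TSV outputs. The exported functions are the
# command-surface of the package; `stages` plays the role of subcommands.

run_config_defaults <- function() list(
  input_dir = NULL,          # directory of dataset files; NULL => simulate
  out_dir = "milkshare_out",
  sim = NULL,                # sim_config(); built from seed/mode when NULL
  mode = "short",
  pseudocount = 0.5,
  n_perm = 999,
  seed = 1L,
  prevalence_threshold = 0.7,
  min_samples = 2, min_abund = 0.02, dominant_abund = 0.15,
  min_related_pairs = 2,
  pair_denominator = "all",  # or "present_both"
  fdr_family = "panel",      # BH within each body-site comparison
  strict_validation = TRUE)

#' Build a pipeline run configuration
#'
#' Flat key-value configuration with validated keys; unknown keys are an
#' error. Every parameter is echoed into the run manifest together with the
#' package version and seed, which suffices to reproduce all outputs.
#'
#' @param ... configuration overrides of the defaults: `input_dir`,
#'   `out_dir`, `sim`, `mode`, `pseudocount`, `n_perm`, `seed`,
#'   `prevalence_threshold`, `min_samples`, `min_abund`, `dominant_abund`,
#'   `min_related_pairs`, `pair_denominator`, `fdr_family`,
#'   `strict_validation`.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("run_config: unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  if (!cfg$mode %in% c("short", "long"))
    stop("run_config: mode must be 'short' or 'long'")
  if (!cfg$pair_denominator %in% c("all", "present_both"))
    stop("run_config: pair_denominator must be 'all' or 'present_both'")
  structure(cfg, class = "run_config")
}

#' Read a dataset directory
#'
#' Loads the standard file set written by [write_dataset()] (counts,
#' metadata, sequences, taxonomy and, when present, the mock reference).
#'
#' @param dir dataset directory.
#' @return list with `table`, `meta`, `records`, `taxonomy`,
#'   `mock_reference` (NULL if absent).
#' @export
read_dataset <- function(dir) {
  ref_path <- file.path(dir, "mock_reference.tsv")
  list(table = read_asv_table(file.path(dir, "counts.tsv")),
       meta = read_sample_meta(file.path(dir, "meta.tsv")),
       records = read_fasta(file.path(dir, "asvs.fasta")),
       taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
       mock_reference = if (file.exists(ref_path)) read_mock_reference(ref_path)
                        else NULL)
}

write_tsv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages (`simulate`, `composition`, `contamination`,
#' `sharing`, or `all`) on a dataset directory or a freshly simulated
#' cohort, writing TSV results and a run manifest under `config$out_dir`.
#' Identical configuration and seed reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @param stages character vector of stage names; `"all"` runs everything.
#' @return list with `manifest` path, `outputs` (named file paths) and the
#'   in-memory stage results, invisibly.
#' @export
run_pipeline <- function(config = run_config(), stages = "all") {
  known <- c("all", "simulate", "composition", "contamination", "sharing")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("run_pipeline: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  if ("all" %in% stages) stages <- known[-1]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0); results <- list()

  if ("simulate" %in% stages || is.null(config$input_dir)) {
    sim <- config$sim
    if (is.null(sim)) sim <- sim_config(mode = config$mode, seed = config$seed)
    dataset <- simulate_cohort(sim)
    sim_dir <- file.path(config$out_dir, "dataset")
    write_dataset(dataset, sim_dir)
    outputs["dataset"] <- sim_dir
    data <- dataset
  } else {
    data <- read_dataset(config$input_dir)
  }

  report <- validate_dataset(data$table, data$meta, data$records,
                             data$taxonomy, mode = config$mode)
  write_tsv_atomic(report, file.path(config$out_dir, "validation_report.tsv"))
  outputs["validation"] <- file.path(config$out_dir, "validation_report.tsv")
  if (config$strict_validation && nrow(report) > 0)
    stop("run_pipeline: dataset failed validation (",
         nrow(report), " finding(s)); see validation_report.tsv")
  results$validation <- report

  bio_types <- c("MILK", "INFANT_ORAL", "INFANT_FAECES", "MATERNAL_FAECES")

  if ("composition" %in% stages) {
    g <- genus_aggregate(data$table, data$taxonomy)
    clr <- clr_transform(g, pseudocount = config$pseudocount)
    d <- aitchison_distances(clr)
    ord <- pcoa_ordination(d)
    keep <- rownames(d) %in% data$meta$sample_id[data$meta$sample_type %in%
                                                   c(bio_types, "NEG_ISOLATION",
                                                     "NEG_LIBPREP")]
    dd <- d[keep, keep]
    fac <- data.frame(
      sample_type = data$meta$sample_type[match(rownames(dd),
                                                data$meta$sample_id)])
    perm <- permanova(dd, fac, n_perm = config$n_perm, seed = config$seed)
    core <- core_genera(g, config$prevalence_threshold,
                        samples = data$meta$sample_id[data$meta$sample_type == "MILK"])
    disp <- display_filter(g, config$min_samples, config$min_abund,
                           config$dominant_abund)
    write_tsv_atomic(data.frame(sample_id = rownames(g$abund), g$abund,
                                check.names = FALSE),
                     file.path(config$out_dir, "genus_abundance.tsv"))
    write_tsv_atomic(data.frame(sample_id = rownames(d), d,
                                check.names = FALSE),
                     file.path(config$out_dir, "aitchison_distances.tsv"))
    write_tsv_atomic(data.frame(sample_id = rownames(ord$coords), ord$coords,
                                var_frac = NA, check.names = FALSE),
                     file.path(config$out_dir, "pcoa_coordinates.tsv"))
    write_tsv_atomic(perm$table, file.path(config$out_dir, "permanova.tsv"))
    write_tsv_atomic(data.frame(genus = core),
                     file.path(config$out_dir, "core_genera_milk.tsv"))
    outputs["composition"] <- file.path(config$out_dir, "permanova.tsv")
    results$composition <- list(genus = g, clr = clr, distances = d,
                                pcoa = ord, permanova = perm, core = core,
                                display = disp)
    if (!is.null(data$mock_reference)) {
      mock_ids <- data$meta$sample_id[data$meta$sample_type == "MOCK"]
      mock_eval <- lapply(setNames(mock_ids, mock_ids), function(sid)
        evaluate_mock(g$abund[sid, ], data$mock_reference))
      results$composition$mock <- mock_eval
      write_tsv_atomic(data.frame(
        sample_id = mock_ids,
        aitchison_distance = vapply(mock_eval, `[[`, numeric(1),
                                    "aitchison_distance"),
        n_missing = vapply(mock_eval, function(x) length(x$missing), integer(1)),
        n_unexpected = vapply(mock_eval, function(x) length(x$unexpected),
                              integer(1))),
        file.path(config$out_dir, "mock_evaluation.tsv"))
    }
  }

  if ("contamination" %in% stages) {
    rep <- contamination_report(data$table, data$meta)
    attr_src <- attribute_source(data$table, data$meta)
    yields <- setNames(data$meta$dna_yield_ng, data$meta$sample_id)
    fr <- setNames(rep$fraction, rep$sample_id)
    corr <- tryCatch(yield_correlation(yields[rep$sample_id], fr),
                     error = function(e) list(rho = NA_real_, p = NA_real_,
                                              n_used = 0, n_dropped = 0))
    per_method <- do.call(rbind, lapply(split(rep, rep$isolation_method),
                                        function(df) data.frame(
      isolation_method = df$isolation_method[1],
      median_pct = round(100 * median(df$fraction, na.rm = TRUE), 1),
      min_pct = round(100 * min(df$fraction, na.rm = TRUE), 1),
      max_pct = round(100 * max(df$fraction, na.rm = TRUE), 1),
      stringsAsFactors = FALSE)))
    write_tsv_atomic(rep, file.path(config$out_dir, "contamination_report.tsv"))
    write_tsv_atomic(attr_src$ranges,
                     file.path(config$out_dir, "contamination_sources.tsv"))
    write_tsv_atomic(per_method,
                     file.path(config$out_dir, "contamination_by_method.tsv"))
    outputs["contamination"] <- file.path(config$out_dir,
                                          "contamination_report.tsv")
    results$contamination <- list(report = rep, sources = attr_src,
                                  per_method = per_method,
                                  yield_correlation = corr)
  }

  if ("sharing" %in% stages) {
    if (!"family_id" %in% names(data$meta) ||
        all(is.na(data$meta$family_id)))
      stop("run_pipeline: sharing stage requires the family_id metadata column")
    comparisons <- intersect(c("INFANT_ORAL", "INFANT_FAECES",
                               "MATERNAL_FAECES"), data$meta$sample_type)
    share_res <- list()
    for (tt in comparisons) {
      pairs <- enumerate_pairs(data$meta, "MILK", tt)
      cand <- select_candidate_genera(data$table, data$taxonomy, pairs,
                                      config$min_related_pairs)
      if (!length(cand)) next
      calls <- do.call(rbind, lapply(cand, function(g)
        classify_pair_sharing(pairs, g, data$table, data$records,
                              data$taxonomy)))
      tests <- sharing_tests(calls, denominator = config$pair_denominator)
      tests$comparison <- attr(pairs, "comparison")
      cmp_tag <- tolower(tt)
      write_tsv_atomic(calls, file.path(
        config$out_dir, paste0("sharing_calls_milk_vs_", cmp_tag, ".tsv")))
      write_tsv_atomic(tests, file.path(
        config$out_dir, paste0("sharing_tests_milk_vs_", cmp_tag, ".tsv")))
      share_res[[tt]] <- list(pairs = pairs, candidates = cand,
                              calls = calls, tests = tests)
    }
    if (config$fdr_family == "global" && length(share_res)) {
      all_tests <- do.call(rbind, lapply(share_res, `[[`, "tests"))
      all_tests$fdr <- p.adjust(all_tests$p, method = "BH")
      all_tests$significance <- significance_stars(all_tests$fdr)
      write_tsv_atomic(all_tests,
                       file.path(config$out_dir, "sharing_tests_global.tsv"))
    }
    # per-genus trees for genera with enough distinct sequences
    tree_lines <- character(0)
    for (tt in names(share_res)) {
      for (g in share_res[[tt]]$candidates) {
        asvs <- intersect(genus_asvs(g, data$taxonomy), colnames(data$table))
        used <- asvs[colSums(data$table[, asvs, drop = FALSE]) > 0]
        if (length(used) < 3) next
        seqs <- setNames(
          data$records$sequence[match(used, data$records$asv_id)], used)
        aln <- progressive_msa(seqs)
        dh <- hamming_matrix(aln)
        tree_lines[paste(tt, g)] <- paste0(g, "\t", tt, "\t",
                                           to_newick(nj_tree(dh)))
      }
    }
    if (length(tree_lines))
      writeLines(c("genus\tcomparison\tnewick", unname(tree_lines)),
                 file.path(config$out_dir, "nj_trees.tsv"))
    outputs["sharing"] <- config$out_dir
    results$sharing <- share_res
  }

  manifest <- c(
    sprintf("package_version\t%s", as.character(utils::packageVersion("milkshare"))),
    sprintf("stages\t%s", paste(stages, collapse = ",")),
    vapply(names(unclass(config)), function(k) {
      v <- config[[k]]
      v <- if (is.null(v)) "" else if (inherits(v, "sim_config"))
        paste0("sim_config(seed=", v$seed, ")") else paste(v, collapse = ",")
      paste0(k, "\t", v)
    }, character(1)))
  manifest_path <- file.path(config$out_dir, "run_manifest.tsv")
  writeLines(manifest, manifest_path)
  invisible(list(manifest = manifest_path, outputs = outputs,
                 results = results))
}
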