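# Synthetic cohort generator: genus ASV pools, mother-infant families with
# planted sharing, kit-specific negative controls and mock communities, plus a
# machine-readable truth log. All stochastic steps run on seeds derived from
# the single config seed so regeneration is bit-identical.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generator calls do not disturb the
#' caller's random number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic sub-seed from a base seed and a string key (kept < 2^31 - 1)
derive_seed <- function(seed, key) {
  h <- as.integer(seed) %% 2147483647L
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% 2147483647
  as.integer(h)
}

#' Default theoretical mock-community composition
#'
#' Eight-genus even-log-distributed bacterial standard used as the positive
#' control reference (relative 16S abundances).
#'
#' @return a [mock_reference()] named vector.
#' @export
default_mock_reference <- function() {
  mock_reference(c(
    Pseudomonas = 0.042, `Escherichia-Shigella` = 0.101, Salmonella = 0.104,
    Limosilactobacillus = 0.184, Enterococcus = 0.099, Staphylococcus = 0.155,
    Listeria = 0.141, Bacillus = 0.174))
}

#' Build a simulation configuration
#'
#' Defaults mirror the pilot-study design: 14 mother-infant families each
#' contributing milk, infant oral, infant faecal and maternal faecal samples,
#' all isolated with one kit; per-method negative controls with 0-5000 reads
#' of kit-specific contaminant ASVs; and one mock community per method drawn
#' around the theoretical reference. Sharing-candidate genera default to the
#' orally/milk-associated genera with planted related-pair sharing probability
#' `p_share` and cosmopolitan background carriage `p_bg` per sample.
#'
#' @param n_families number of mother-infant families.
#' @param sample_types body-site sample types generated per family.
#' @param mode amplicon mode: `"short"` (400-431 bp window, 420 bp amplicons)
#'   or `"long"` (1900-3000 bp window, 2500 bp amplicons).
#' @param genera character vector of sharing-candidate genus names.
#' @param p_share per-genus probability that a related (milk, other-site) pair
#'   is planted with an identical ASV.
#' @param p_bg per-sample carriage probability of the genus' cosmopolitan pool
#'   ASV (background sharing between unrelated pairs arises only through it).
#' @param prevalence per-sample-type detection probability of each genus
#'   (single value recycled over types).
#' @param abundance_sdlog log-normal sd of per-genus relative abundance.
#' @param depth named read depths per sample type (log-normal jitter, sd 0.2).
#' @param isolation_methods kits in the design (each gets its own disjoint
#'   contaminant pool and negative controls).
#' @param n_controls isolation negative controls per method.
#' @param n_libprep_controls library-preparation negative controls.
#' @param control_depth_max upper bound of the uniform control read depth.
#' @param contaminant_genera genus labels for kit contaminant ASVs.
#' @param injection_rate probability that each contaminant ASV of a sample's
#'   kit is injected into that biological sample.
#' @param contam_frac expected contaminated read fraction at the reference
#'   DNA yield (the realised fraction scales inversely with the sample's
#'   yield, so low-yield samples are more contaminated).
#' @param mock_reference theoretical mock composition.
#' @param mock_depth,mock_dispersion mock sample read depth and multiplicative
#'   log-normal noise sd.
#' @param substitution_rate per-site substitution probability when deriving
#'   pool ASVs from the genus ancestor sequence.
#' @param seed integer seed recorded in the output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_families = 14,
                       sample_types = c("MILK", "INFANT_ORAL",
                                        "INFANT_FAECES", "MATERNAL_FAECES"),
                       mode = c("short", "long"),
                       genera = c("Streptococcus", "Staphylococcus", "Rothia",
                                  "Gemella", "Veillonella"),
                       p_share = 0.5,
                       p_bg = 0.02,
                       prevalence = 0.8,
                       abundance_sdlog = 1,
                       depth = c(MILK = 15000, INFANT_ORAL = 20000,
                                 INFANT_FAECES = 30000, MATERNAL_FAECES = 30000),
                       isolation_methods = "PS",
                       n_controls = 2,
                       n_libprep_controls = 1,
                       control_depth_max = 5000,
                       contaminant_genera = c("Cutibacterium", "Enhydrobacter",
                                              "Escherichia-Shigella", "Pelomonas"),
                       injection_rate = 0.5,
                       contam_frac = 0.03,
                       mock_reference = default_mock_reference(),
                       mock_depth = 20000,
                       mock_dispersion = 0.3,
                       substitution_rate = 0.02,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (length(genera) == 0) stop("sim_config: empty genera list")
  p <- c(p_share = p_share, p_bg = p_bg, prevalence = prevalence,
         injection_rate = injection_rate, contam_frac = contam_frac)
  if (any(p < 0 | p > 1))
    stop("sim_config: probabilities must lie in [0, 1]: ",
         paste(names(p)[p < 0 | p > 1], collapse = ", "))
  if (any(depth < 0) || control_depth_max < 0 || mock_depth < 0)
    stop("sim_config: read depths must be >= 0")
  missing_depth <- setdiff(sample_types, names(depth))
  if (length(missing_depth))
    stop("sim_config: no depth for sample type(s): ",
         paste(missing_depth, collapse = ", "))
  cfg <- list(n_families = n_families, sample_types = sample_types,
              mode = mode,
              amplicon_length = if (mode == "short") 420L else 2500L,
              genera = genera, p_share = p_share, p_bg = p_bg,
              prevalence = prevalence, abundance_sdlog = abundance_sdlog,
              depth = depth, isolation_methods = isolation_methods,
              n_controls = n_controls,
              n_libprep_controls = n_libprep_controls,
              control_depth_max = control_depth_max,
              contaminant_genera = contaminant_genera,
              injection_rate = injection_rate, contam_frac = contam_frac,
              mock_reference = mock_reference, mock_depth = mock_depth,
              mock_dispersion = mock_dispersion,
              substitution_rate = substitution_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(length_bp)
  paste(sample(c("A", "C", "G", "T"), length_bp, replace = TRUE), collapse = "")

mutate_sequence <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

#' Generate a genus ASV pool
#'
#' Derives `n_asvs` distinct sequences from a random ancestor by per-site
#' substitutions (no indels, so all sequences share the ancestor's length and
#' Hamming distances are defined without alignment) and records the true
#' pairwise Hamming distances.
#'
#' @param genus genus name (used in ASV ids).
#' @param n_asvs number of distinct pool sequences.
#' @param length_bp amplicon length; must fall inside the `mode` window.
#' @param substitution_rate per-site substitution probability in (0, 1).
#' @param seed integer seed; same seed gives a bit-identical pool.
#' @param mode amplicon mode governing the admissible length window.
#' @return list with `genus`, `ancestor`, `records` (asv_id, sequence,
#'   length_bp) and `distances` (true pairwise Hamming matrix).
#' @export
generate_genus_pool <- function(genus, n_asvs, length_bp, substitution_rate,
                                seed, mode = c("short", "long")) {
  mode <- match.arg(mode)
  win <- LENGTH_WINDOWS[[mode]]
  if (length_bp < win[1] || length_bp > win[2])
    stop(sprintf("generate_genus_pool: length %d bp outside %d-%d bp window (%s mode)",
                 length_bp, win[1], win[2], mode))
  if (substitution_rate < 0 || substitution_rate >= 1)
    stop("generate_genus_pool: substitution_rate must be in [0, 1)")
  if (substitution_rate == 0 && n_asvs > 1)
    stop("generate_genus_pool: cannot derive ", n_asvs,
         " distinct sequences at substitution rate 0")
  with_seed(seed, {
    ancestor <- random_dna(length_bp)
    seqs <- character(0)
    attempts <- 0
    while (length(seqs) < n_asvs) {
      cand <- if (length(seqs) == 0 && substitution_rate == 0) ancestor
              else mutate_sequence(ancestor, max(substitution_rate, 0))
      if (length(seqs) == 0 || !cand %in% seqs) seqs <- c(seqs, cand)
      attempts <- attempts + 1
      if (attempts > 100 * n_asvs)
        stop("generate_genus_pool: could not derive ", n_asvs,
             " distinct sequences; raise substitution_rate or length")
    }
    ids <- sprintf("%s_ASV%03d", gsub("[^A-Za-z0-9]", "", genus), seq_len(n_asvs))
    d <- matrix(0L, n_asvs, n_asvs, dimnames = list(ids, ids))
    if (n_asvs > 1) {
      chars <- do.call(rbind, strsplit(seqs, ""))
      for (i in 1:(n_asvs - 1)) for (j in (i + 1):n_asvs)
        d[i, j] <- d[j, i] <- sum(chars[i, ] != chars[j, ])
    }
    list(genus = genus, ancestor = ancestor,
         records = data.frame(asv_id = ids, sequence = seqs,
                              length_bp = nchar(seqs), stringsAsFactors = FALSE),
         distances = d)
  })
}

#' Simulate one mock-community sample
#'
#' Expected fractions are the reference perturbed by multiplicative log-normal
#' noise and renormalized; counts are one multinomial draw of `depth` reads.
#' At `dispersion = 0` the expected fractions equal the reference exactly.
#'
#' @param reference a [mock_reference()] vector (sums to 1).
#' @param depth total reads; 0 yields an all-zero column with a warning.
#' @param dispersion sd of the log-normal perturbation.
#' @param seed integer seed.
#' @return named integer vector of per-genus read counts.
#' @export
simulate_mock_sample <- function(reference, depth, dispersion, seed) {
  reference <- mock_reference(reference)
  if (depth == 0) {
    warning("simulate_mock_sample: depth 0, returning all-zero column")
    return(setNames(integer(length(reference)), names(reference)))
  }
  with_seed(seed, {
    w <- reference * exp(rnorm(length(reference), 0, dispersion))
    w <- w / sum(w)
    counts <- as.integer(rmultinom(1, depth, w))
    setNames(counts, names(reference))
  })
}

# disjoint per-method contaminant pools: every method gets its own ASVs drawn
# from independent ancestors, so no contaminant sequence recurs across kits
contaminant_pools <- function(config) {
  pools <- list()
  for (m in c(config$isolation_methods, "LIBPREP")) {
    recs <- lapply(seq_along(config$contaminant_genera), function(i) {
      g <- config$contaminant_genera[i]
      pool <- generate_genus_pool(
        paste0(g, "_", m), 1, config$amplicon_length,
        config$substitution_rate,
        derive_seed(config$seed, paste0("contam/", m, "/", g)),
        mode = config$mode)
      data.frame(asv_id = pool$records$asv_id,
                 sequence = pool$records$sequence,
                 length_bp = pool$records$length_bp,
                 genus = g, stringsAsFactors = FALSE)
    })
    pools[[m]] <- do.call(rbind, recs)
  }
  pools
}

#' Simulate negative-control columns and contaminant injection
#'
#' Draws per-method isolation negative controls and library-preparation
#' controls with low read depths (uniform on 0 to `control_depth_max`), spread
#' over the method's contaminant ASV pool, and injects the same contaminant
#' ASVs into the supplied biological sample columns at `injection_rate`. The
#' injected read fraction scales inversely with the sample's DNA yield. Every
#' injected (sample, ASV) is logged.
#'
#' @param config a [sim_config()].
#' @param pools per-method contaminant record tables (built from `config` when
#'   omitted).
#' @param bio_counts optional biological samples x ASV matrix to inject into.
#' @param bio_meta metadata for `bio_counts` rows (needs `sample_id`,
#'   `isolation_method`, `dna_yield_ng`).
#' @return list with `control_counts` (controls x contaminant ASVs),
#'   `control_meta`, `records`, `taxonomy`, `bio_extra` (samples x contaminant
#'   ASVs injection matrix) and `truth` (sample_id, asv_id, method, reads).
#' @export
simulate_negative_controls <- function(config, pools = contaminant_pools(config),
                                       bio_counts = NULL, bio_meta = NULL) {
  all_recs <- do.call(rbind, lapply(names(pools), function(m)
    cbind(pools[[m]], method = m, stringsAsFactors = FALSE)))
  asv_ids <- all_recs$asv_id
  ctrl_rows <- list(); ctrl_meta <- list()
  add_ctrl <- function(id, type, method, pool, seed_key) {
    with_seed(derive_seed(config$seed, seed_key), {
      depth <- floor(runif(1, 0, config$control_depth_max + 1))
      row <- setNames(integer(length(asv_ids)), asv_ids)
      if (depth > 0) {
        k <- nrow(pool)
        base <- if (depth >= k) rep(1L, k) else
          as.integer(seq_len(k) %in% sample.int(k, depth))
        rest <- depth - sum(base)
        extra <- if (rest > 0) as.integer(rmultinom(1, rest, rlnorm(k, 0, 1)))
                 else integer(k)
        row[pool$asv_id] <- base + extra
      }
      ctrl_rows[[id]] <<- row
      ctrl_meta[[id]] <<- data.frame(
        sample_id = id, family_id = NA_character_, sample_type = type,
        isolation_method = method, sequencing_method =
          if (config$mode == "short") "SHORT_16S" else "LONG_16S_ITS_23S",
        replicate = length(ctrl_meta) + 1L, dna_yield_ng = 0,
        stringsAsFactors = FALSE)
    })
  }
  for (m in config$isolation_methods)
    for (r in seq_len(config$n_controls))
      add_ctrl(sprintf("NEG_%s_%d", m, r), "NEG_ISOLATION", m, pools[[m]],
               paste0("negctrl/", m, "/", r))
  for (r in seq_len(config$n_libprep_controls))
    add_ctrl(sprintf("NEG_LIBPREP_%d", r), "NEG_LIBPREP", "NONE",
             pools[["LIBPREP"]], paste0("negctrl/LIBPREP/", r))
  control_counts <- do.call(rbind, ctrl_rows)
  control_meta <- do.call(rbind, ctrl_meta)
  control_meta$replicate <- stats::ave(seq_len(nrow(control_meta)),
                                       control_meta$isolation_method,
                                       control_meta$sample_type,
                                       FUN = seq_along)

  truth <- list(); bio_extra <- NULL
  if (!is.null(bio_counts)) {
    bio_extra <- matrix(0L, nrow(bio_counts), length(asv_ids),
                        dimnames = list(rownames(bio_counts), asv_ids))
    yield_ref <- stats::median(bio_meta$dna_yield_ng, na.rm = TRUE)
    for (i in seq_len(nrow(bio_counts))) {
      sid <- rownames(bio_counts)[i]
      method <- bio_meta$isolation_method[bio_meta$sample_id == sid]
      pool <- pools[[method]]
      if (is.null(pool)) next
      with_seed(derive_seed(config$seed, paste0("inject/", sid)), {
        sel <- runif(nrow(pool)) < config$injection_rate
        if (any(sel)) {
          yield <- bio_meta$dna_yield_ng[bio_meta$sample_id == sid]
          frac <- min(config$contam_frac * yield_ref / max(yield, 1e-6), 0.4)
          depth <- sum(bio_counts[i, ])
          n_reads <- max(sum(sel), rbinom(1, depth, frac))
          alloc <- as.integer(rmultinom(1, n_reads - sum(sel), rep(1, sum(sel)))) + 1L
          bio_extra[i, pool$asv_id[sel]] <- alloc
          truth[[length(truth) + 1]] <- data.frame(
            sample_id = sid, asv_id = pool$asv_id[sel], method = method,
            reads = alloc, stringsAsFactors = FALSE)
        }
      })
    }
  }
  ctrl_truth <- do.call(rbind, c(list(data.frame(
    sample_id = character(), asv_id = character(), method = character(),
    reads = integer(), stringsAsFactors = FALSE)), truth))
  list(control_counts = control_counts, control_meta = control_meta,
       records = all_recs[, c("asv_id", "sequence", "length_bp")],
       taxonomy = data.frame(asv_id = all_recs$asv_id, genus = all_recs$genus,
                             species = "UNCLASSIFIED", stringsAsFactors = FALSE),
       bio_extra = bio_extra, truth = ctrl_truth)
}

#' Simulate a full mother-infant cohort
#'
#' Generates one sample of every configured body-site type per family. For
#' each genus, every (family, sample type) owns a private pool ASV; for each
#' related (milk, other-site) pair a sharing event is planted with probability
#' `p_share` by placing one family-and-comparison-specific ASV in both
#' members, and each sample additionally carries the genus' single
#' cosmopolitan ASV with probability `p_bg` (the only route to unrelated-pair
#' sharing). Per-sample genus abundances are log-normal, renormalized, and
#' read counts are multinomial at the configured depth. Negative controls,
#' contaminant injection and mock communities are appended, and every planted
#' event is recorded in the truth log.
#'
#' @param config a [sim_config()].
#' @return list with `table` ([asv_table()]), `meta`, `records`, `taxonomy`,
#'   `mock_reference`, `truth` (list `sharing`, `contaminants`) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$genera) == 0) stop("simulate_cohort: empty genera list")
  nf <- config$n_families
  families <- sprintf("F%02d", seq_len(nf))
  types <- config$sample_types
  other_types <- setdiff(types, "MILK")
  len <- config$amplicon_length

  # genus pools: 1 cosmopolitan + per-family (one per type + one per milk-X
  # comparison) private ASVs
  per_family <- length(types) + length(other_types)
  n_pool <- 1 + nf * per_family
  pools <- lapply(config$genera, function(g)
    generate_genus_pool(g, n_pool, len, config$substitution_rate,
                        derive_seed(config$seed, paste0("pool/", g)),
                        mode = config$mode))
  names(pools) <- config$genera

  # index helpers into each genus pool
  cosmo_idx <- 1L
  own_idx <- function(f, t)
    as.integer(1 + (f - 1) * per_family + match(t, types))
  share_idx <- function(f, t)
    as.integer(1 + (f - 1) * per_family + length(types) + match(t, other_types))

  sample_ids <- as.vector(t(outer(families, types, paste, sep = "_")))
  sample_family <- rep(families, each = length(types))
  sample_type <- rep(types, nf)

  # planted sharing decisions (family x genus x comparison)
  sharing <- list()
  planted <- array(FALSE, dim = c(nf, length(config$genera), length(other_types)))
  for (fi in seq_len(nf)) for (gi in seq_along(config$genera))
    for (ti in seq_along(other_types)) {
      g <- config$genera[gi]; t <- other_types[ti]
      hit <- with_seed(
        derive_seed(config$seed, paste0("share/", families[fi], "/", g, "/", t)),
        runif(1) < config$p_share)
      planted[fi, gi, ti] <- hit
      sharing[[length(sharing) + 1]] <- data.frame(
        family_id = families[fi], genus = g,
        comparison = paste0("MILK_vs_", t), planted = hit,
        asv_id = if (hit) pools[[g]]$records$asv_id[share_idx(fi, t)]
                 else NA_character_,
        stringsAsFactors = FALSE)
    }
  sharing <- do.call(rbind, sharing)

  # per-sample ASV content and counts
  all_ids <- unlist(lapply(pools, function(p) p$records$asv_id))
  counts <- matrix(0L, length(sample_ids), length(all_ids),
                   dimnames = list(sample_ids, all_ids))
  yields <- numeric(length(sample_ids))
  yield_meanlog <- c(MILK = log(240), INFANT_ORAL = log(50),
                     INFANT_FAECES = log(500), MATERNAL_FAECES = log(800))
  for (si in seq_along(sample_ids)) {
    sid <- sample_ids[si]
    fi <- match(sample_family[si], families)
    t <- sample_type[si]
    with_seed(derive_seed(config$seed, paste0("sample/", sid)), {
      yields[si] <- rlnorm(1, yield_meanlog[[t]] %||% log(100), 0.6)
      depth <- max(1, round(rlnorm(1, log(config$depth[[t]]), 0.2)))
      member <- list()   # per genus: pool indices present in this sample
      for (gi in seq_along(config$genera)) {
        g <- config$genera[gi]
        idx <- integer(0)
        if (runif(1) < config$prevalence) idx <- own_idx(fi, t)
        if (runif(1) < config$p_bg) idx <- c(idx, cosmo_idx)
        if (t == "MILK") {
          ti_hit <- which(planted[fi, gi, ])
          if (length(ti_hit))
            idx <- c(idx, vapply(other_types[ti_hit],
                                 function(tt) share_idx(fi, tt), integer(1)))
        } else {
          ti <- match(t, other_types)
          if (planted[fi, gi, ti]) idx <- c(idx, share_idx(fi, t))
        }
        member[[g]] <- unique(idx)
      }
      if (all(lengths(member) == 0)) {
        g <- config$genera[1 + (si %% length(config$genera))]
        member[[g]] <- own_idx(fi, t)   # avoid a zero-read biological sample
      }
      w <- numeric(0); ids <- character(0)
      for (g in names(member)) {
        if (length(member[[g]]) == 0) next
        gw <- rlnorm(1, 0, config$abundance_sdlog)
        aw <- rlnorm(length(member[[g]]), 0, 1)
        w <- c(w, gw * aw / sum(aw))
        ids <- c(ids, pools[[g]]$records$asv_id[member[[g]]])
      }
      draw <- as.integer(rmultinom(1, depth, w / sum(w)))
      # planted and carried ASVs must be detectable (count >= 1)
      draw[draw == 0] <- 1L
      counts[si, ids] <- draw
    })
  }

  meta <- data.frame(
    sample_id = sample_ids, family_id = sample_family,
    sample_type = sample_type,
    isolation_method = config$isolation_methods[1],
    sequencing_method = if (config$mode == "short") "SHORT_16S" else "LONG_16S_ITS_23S",
    replicate = 1L, dna_yield_ng = round(yields, 1),
    stringsAsFactors = FALSE)

  records <- do.call(rbind, lapply(pools, function(p) p$records))
  rownames(records) <- NULL
  taxonomy <- do.call(rbind, lapply(pools, function(p)
    data.frame(asv_id = p$records$asv_id, genus = p$genus,
               species = "UNCLASSIFIED", stringsAsFactors = FALSE)))
  rownames(taxonomy) <- NULL

  # negative controls + contaminant injection
  cpools <- contaminant_pools(config)
  neg <- simulate_negative_controls(config, cpools, bio_counts = counts,
                                    bio_meta = meta)
  bio_full <- cbind(counts, neg$bio_extra)
  ctrl_block <- matrix(0L, nrow(neg$control_counts), ncol(counts),
                       dimnames = list(rownames(neg$control_counts),
                                       colnames(counts)))
  ctrl_full <- cbind(ctrl_block, neg$control_counts)
  table <- rbind(bio_full, ctrl_full)
  meta <- rbind(meta, neg$control_meta)
  records <- rbind(records, neg$records)
  taxonomy <- rbind(taxonomy, neg$taxonomy)

  # mock communities: one per isolation method, one ASV per reference genus
  ref <- config$mock_reference
  mock_pool <- lapply(names(ref), function(g)
    generate_genus_pool(paste0(g, "_MOCK"), 1, len, config$substitution_rate,
                        derive_seed(config$seed, paste0("mockpool/", g)),
                        mode = config$mode)$records)
  mock_recs <- do.call(rbind, mock_pool)
  mock_cols <- matrix(0L, nrow(table), nrow(mock_recs),
                      dimnames = list(rownames(table), mock_recs$asv_id))
  table <- cbind(table, mock_cols)
  for (m in config$isolation_methods) {
    col <- simulate_mock_sample(ref, config$mock_depth, config$mock_dispersion,
                                derive_seed(config$seed, paste0("mock/", m)))
    row <- setNames(integer(ncol(table)), colnames(table))
    row[mock_recs$asv_id] <- as.integer(col)
    sid <- paste0("MOCK_", m)
    table <- rbind(table, matrix(row, 1, dimnames = list(sid, names(row))))
    meta <- rbind(meta, data.frame(
      sample_id = sid, family_id = NA_character_, sample_type = "MOCK",
      isolation_method = m, sequencing_method = meta$sequencing_method[1],
      replicate = 1L, dna_yield_ng = round(with_seed(
        derive_seed(config$seed, paste0("mockyield/", m)),
        rlnorm(1, log(100), 0.5)), 1),
      stringsAsFactors = FALSE))
  }
  records <- rbind(records, mock_recs)
  taxonomy <- rbind(taxonomy, data.frame(
    asv_id = mock_recs$asv_id, genus = names(ref), species = "UNCLASSIFIED",
    stringsAsFactors = FALSE))

  list(table = asv_table(table), meta = meta, records = records,
       taxonomy = taxonomy, mock_reference = ref,
       truth = list(sharing = sharing, contaminants = neg$truth),
       pools = pools, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated dataset to a directory
#'
#' Emits the standard file set (`counts.tsv`, `meta.tsv`, `asvs.fasta`,
#' `taxonomy.tsv`, `mock_reference.tsv`) plus the truth logs
#' (`truth_sharing.tsv`, `truth_contaminants.tsv`) and a header file recording
#' the generator parameters and seed.
#'
#' @param dataset a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_asv_table(dataset$table, file.path(dir, "counts.tsv"))
  write_sample_meta(dataset$meta, file.path(dir, "meta.tsv"))
  write_fasta(dataset$records, file.path(dir, "asvs.fasta"))
  write.table(dataset$taxonomy, file.path(dir, "taxonomy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(genus = names(dataset$mock_reference),
                         expected_fraction = as.numeric(dataset$mock_reference)),
              file.path(dir, "mock_reference.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$truth$sharing, file.path(dir, "truth_sharing.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$truth$contaminants,
              file.path(dir, "truth_contaminants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  keep <- vapply(cfg, function(x) is.atomic(x) && length(x) >= 1, logical(1))
  lines <- vapply(names(cfg)[keep], function(k)
    paste0(k, "\t", paste(cfg[[k]], collapse = ",")), character(1))
  writeLines(c("# synthetic dataset: generator parameters (not estimates of any real cohort)",
               lines), file.path(dir, "generator_params.tsv"))
  invisible(dir)
}
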