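#' Simulation configuration
#'
#' Defines the synthetic study emulating the feeding-trial design: four
#' time points (0d, 3w, 5w, 7w), 3 mRNA and 2 miRNA replicates per time
#' point, negative-binomial counts with log-normal baselines, planted
#' stage-wise differential expression (a step change from the later time
#' point of the stage onward), planted gut checkpoint categories (perturbed
#' at 3w/5w, restored at 7w) and liver checkpoint categories (perturbed
#' from 3w onward), planted signed miRNA-to-target couplings, planted
#' enriched pathways, and group-level phenotype records.
#'
#' @param seed Mandatory integer seed; every draw derives from it.
#' @param n_genes,n_mirnas Feature counts (defaults 2000 genes, 200 miRNAs).
#' @param reps_mrna,reps_mirna Replicates per time point (3 and 2).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline mean
#'   parameters (defaults `log(100)`, 1).
#' @param dispersion NB dispersion (`Var = mu + alpha mu^2`; default 0.1).
#' @param n_de_per_stage Planted DE genes per stage per tissue (default 100).
#' @param de_lfc Magnitude of planted log2 fold changes (default 2; half of
#'   the planted genes go up, half down).
#' @param n_mirna_de_per_stage Planted DE miRNAs per stage (default 30).
#' @param n_checkpoint_categories Size of the checkpoint category pool
#'   (default 40); the first 5 are planted as gut checkpoints, the next 5
#'   as liver checkpoints.
#' @param genes_per_category Member genes per category (default 5).
#' @param checkpoint_effect Planted category effect in log2 units
#'   (default 1.5).
#' @param annotate_de_genes Also annotate the planted stage-DE genes into
#'   immune categories (default `TRUE`), so classification, enrichment and
#'   the report tables see immune DE genes.
#' @param n_coupled_pairs Planted miRNA-target couplings (default 40).
#' @param frac_negative_couplings Fraction with negative sign (default 0.75).
#' @param coupling_beta Coupling strength `beta` (default 1): a target's
#'   mean at time t is its baseline times `2^(sign * beta * z(t))`, `z` the
#'   z-scored realized profile of the coupled miRNA.
#' @param n_decoy_pairs Random uncoupled target-map pairs (default 200).
#' @param n_decoy_sets Decoy gene sets (default 25, 10 genes each).
#' @param depth_sdlog Log-normal sd of per-sample depth factors
#'   (default 0.15).
#' @param phenotype_noise_cv Per-cage coefficient of variation of the
#'   phenotype records (default 0.03; 0 gives the configured means exactly).
#' @return Object of class `sim_config` (a list).
#' @export
sim_config <- function(seed,
                       n_genes = 2000, n_mirnas = 200,
                       reps_mrna = 3, reps_mirna = 2,
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       dispersion = 0.1,
                       n_de_per_stage = 100, de_lfc = 2,
                       n_mirna_de_per_stage = 30,
                       n_checkpoint_categories = 40,
                       genes_per_category = 5,
                       checkpoint_effect = 1.5,
                       annotate_de_genes = TRUE,
                       n_coupled_pairs = 40,
                       frac_negative_couplings = 0.75,
                       coupling_beta = 1,
                       n_decoy_pairs = 200,
                       n_decoy_sets = 25,
                       depth_sdlog = 0.15,
                       phenotype_noise_cv = 0.03) {
  if (missing(seed) || is.null(seed) || is.na(seed)) stop("seed is mandatory")
  seed <- as.integer(seed %% 2000000000L)
  cfg <- as.list(environment())
  n_blocks <- 3 * n_de_per_stage * 2 + n_coupled_pairs +
    n_checkpoint_categories * genes_per_category
  if (n_genes < n_blocks + 100) {
    stop("n_genes too small for the planted blocks (need >= ",
         n_blocks + 100, ")")
  }
  if (3 * n_mirna_de_per_stage > n_mirnas) {
    stop("too many planted DE miRNAs for n_mirnas")
  }
  structure(cfg, class = "sim_config")
}

# Deterministic design: feature ids, block assignments, planted effects and
# the per-time-point design means (everything except count noise and the
# realized miRNA coupling profiles). Seeded by cfg$seed alone.
sim_design <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tps <- trial_timepoints()
  stages <- names(stage_definitions())
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  mirna_ids <- sprintf("mir%03d", seq_len(cfg$n_mirnas))

  nde <- cfg$n_de_per_stage
  npair <- cfg$n_coupled_pairs
  ncat <- cfg$n_checkpoint_categories
  gpc <- cfg$genes_per_category

  idx <- 0
  take <- function(n) { out <- idx + seq_len(n); idx <<- idx + n; out }
  gut_de_idx <- stats::setNames(lapply(stages, function(s) take(nde)), stages)
  target_idx <- take(npair)
  cat_idx <- matrix(take(ncat * gpc), nrow = ncat, byrow = TRUE)
  liver_de_idx <- stats::setNames(lapply(stages, function(s) take(nde)), stages)
  null_idx <- (idx + 1):cfg$n_genes

  # planted per-stage signed lfcs: first half up, second half down
  signed_lfc <- function(n) cfg$de_lfc * rep(c(1, -1), length.out = n)

  plant <- function(de_idx) {
    do.call(rbind, lapply(stages, function(s) {
      ii <- de_idx[[s]]
      data.frame(feature_id = gene_ids[ii],
                 stage = rep(s, length(ii)),
                 lfc = signed_lfc(length(ii)))
    }))
  }
  gut_plant <- plant(gut_de_idx)
  liver_plant <- plant(liver_de_idx)

  nmde <- cfg$n_mirna_de_per_stage
  mir_idx <- stats::setNames(lapply(seq_along(stages), function(i) {
    (i - 1) * nmde + seq_len(nmde)
  }), stages)
  mirna_plant <- do.call(rbind, lapply(stages, function(s) {
    ii <- mir_idx[[s]]
    data.frame(feature_id = mirna_ids[ii],
               stage = rep(s, length(ii)),
               lfc = signed_lfc(length(ii)))
  }))

  # effect activation: a stage's step change turns on at its later time
  # point and persists; checkpoints are perturbed transiently (gut) or
  # persistently (liver)
  stage_on <- list(early = c("3w", "5w", "7w"), middle = c("5w", "7w"),
                   late = c("7w"))

  # categories: round-robin over the nine processes
  procs <- immune_process_labels()
  cat_names <- sprintf("IC%02d", seq_len(ncat))
  cat_process <- procs[((seq_len(ncat) - 1) %% length(procs)) + 1]
  chk_gut <- cat_names[seq_len(min(5, ncat))]
  chk_liver <- cat_names[5 + seq_len(min(5, max(0, ncat - 5)))]

  # signed couplings: miRNAs cycled from the planted DE miRNAs; negative
  # and positive pairs interleaved so both signs occur in every stage
  n_neg <- round(cfg$frac_negative_couplings * npair)
  idx_p <- seq_len(npair)
  pair_sign <- ifelse(ceiling(idx_p * n_neg / max(1, npair)) -
                      ceiling((idx_p - 1) * n_neg / max(1, npair)) == 1,
                      -1, 1)
  pair_mirna_row <- ((seq_len(npair) - 1) %% nrow(mirna_plant)) + 1
  pair_truth <- data.frame(
    mirna_id = mirna_plant$feature_id[pair_mirna_row],
    gene_id = gene_ids[target_idx],
    beta = rep(cfg$coupling_beta, npair),
    sign = ifelse(pair_sign < 0, "negative", "positive"),
    stage = mirna_plant$stage[pair_mirna_row]
  )

  # planted pathways: per stage, 8 up-planted gut genes + 2 null genes
  pathway_sets <- stats::setNames(lapply(stages, function(s) {
    up <- gut_plant$feature_id[gut_plant$stage == s & gut_plant$lfc > 0]
    c(up[seq_len(min(8, length(up)))], gene_ids[null_idx[1:2]])
  }), paste0("planted_", stages))
  decoy_pool <- gene_ids[null_idx[-(1:2)]]
  decoy_sets <- stats::setNames(lapply(seq_len(cfg$n_decoy_sets), function(i) {
    sample(decoy_pool, 10)
  }), sprintf("decoy_%02d", seq_len(cfg$n_decoy_sets)))

  # decoy target-map pairs: random, excluding planted pairs
  decoys <- data.frame(
    mirna_id = sample(mirna_ids, cfg$n_decoy_pairs, replace = TRUE),
    gene_id = sample(gene_ids[c(cat_idx, null_idx)], cfg$n_decoy_pairs,
                     replace = TRUE)
  )
  decoys <- decoys[!duplicated(paste(decoys$mirna_id, decoys$gene_id)), ]

  baselines_gut <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog,
                                 cfg$baseline_sdlog)
  baselines_liver <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog,
                                   cfg$baseline_sdlog)
  baselines_mirna <- stats::rlnorm(cfg$n_mirnas, cfg$baseline_meanlog,
                                   cfg$baseline_sdlog)

  # design mean matrices (features x time points), before coupling
  mean_matrix <- function(base, ids, plant, chk_cats, chk_tps) {
    mu <- matrix(base, nrow = length(ids), ncol = length(tps),
                 dimnames = list(ids, tps))
    for (i in seq_len(nrow(plant))) {
      on <- stage_on[[plant$stage[i]]]
      mu[plant$feature_id[i], on] <- mu[plant$feature_id[i], on] *
        2^plant$lfc[i]
    }
    for (ci in seq_along(cat_names)) {
      if (!(cat_names[ci] %in% chk_cats)) next
      members <- gene_ids[cat_idx[ci, ]]
      mu[members, chk_tps] <- mu[members, chk_tps] * 2^cfg$checkpoint_effect
    }
    mu
  }
  mu_gut <- mean_matrix(baselines_gut, gene_ids, gut_plant,
                        chk_gut, c("3w", "5w"))
  mu_liver <- mean_matrix(baselines_liver, gene_ids, liver_plant,
                          chk_liver, c("3w", "5w", "7w"))
  mu_mirna <- matrix(baselines_mirna, nrow = cfg$n_mirnas, ncol = length(tps),
                     dimnames = list(mirna_ids, tps))
  for (i in seq_len(nrow(mirna_plant))) {
    on <- stage_on[[mirna_plant$stage[i]]]
    mu_mirna[mirna_plant$feature_id[i], on] <-
      mu_mirna[mirna_plant$feature_id[i], on] * 2^mirna_plant$lfc[i]
  }

  list(
    gene_ids = gene_ids, mirna_ids = mirna_ids, timepoints = tps,
    gut_plant = gut_plant, liver_plant = liver_plant,
    mirna_plant = mirna_plant,
    target_ids = gene_ids[target_idx],
    cat_names = cat_names, cat_process = cat_process,
    cat_members = lapply(seq_len(ncat), function(ci) gene_ids[cat_idx[ci, ]]),
    chk_gut = chk_gut, chk_liver = chk_liver,
    pair_truth = pair_truth,
    pathway_sets = pathway_sets, decoy_sets = decoy_sets,
    decoy_pairs = decoys,
    mu_gut = mu_gut, mu_liver = mu_liver, mu_mirna = mu_mirna
  )
}

nb_draw <- function(mu_matrix, reps, dispersion, depth_sdlog, tissue,
                    id_prefix) {
  tps <- colnames(mu_matrix)
  n_samples <- length(tps) * reps
  depth <- stats::rlnorm(n_samples, 0, depth_sdlog)
  counts <- matrix(0L, nrow = nrow(mu_matrix), ncol = n_samples,
                   dimnames = list(rownames(mu_matrix), NULL))
  sheet <- data.frame(sample_id = character(n_samples), tissue = tissue,
                      timepoint = rep(tps, each = reps),
                      replicate = rep(seq_len(reps), times = length(tps)))
  j <- 0
  for (tp in tps) {
    for (r in seq_len(reps)) {
      j <- j + 1
      sheet$sample_id[j] <- sprintf("%s_%s_r%d", id_prefix, tp, r)
      counts[, j] <- stats::rnbinom(nrow(mu_matrix),
                                    mu = mu_matrix[, tp] * depth[j],
                                    size = 1 / dispersion)
    }
  }
  colnames(counts) <- sheet$sample_id
  count_matrix(counts, sheet)
}

#' Simulate count matrices with planted truth
#'
#' Draws gut mRNA, liver mRNA and gut miRNA count matrices from the
#' negative-binomial design of [sim_config()], including per-sample depth
#' factors. miRNA counts are drawn first; each planted coupling then
#' multiplies its target's design mean at time t by
#' `2^(sign * beta * z(t))`, where `z` is the z-scored realized
#' per-time-point mean `log2(normalized + 1)` profile of the coupled miRNA,
#' before the mRNA counts are drawn. Deterministic under the config seed.
#'
#' @param cfg A `sim_config`.
#' @return List with `gut_mrna`, `liver_mrna`, `gut_mirna`
#'   (`count_matrix` objects) and `truth` (see details). The truth carries
#'   the designed plantings (`stage_de_planted`, `checkpoint_truth`,
#'   `pair_truth`) and the full realized DE truth per tissue and stage
#'   (`true_de`: every feature whose design means differ by more than 0.5
#'   log2 units across the contrast, including coupling- and
#'   checkpoint-induced changes).
#' @export
simulate_counts <- function(cfg) {
  des <- sim_design(cfg)
  set.seed(cfg$seed + 1L)

  gut_mirna <- nb_draw(des$mu_mirna, cfg$reps_mirna, cfg$dispersion,
                       cfg$depth_sdlog, "gut", "mirgut")

  # realized miRNA z-profiles drive the coupled targets
  mir_prof <- timepoint_profile(gut_mirna)
  mu_gut <- des$mu_gut
  for (i in seq_len(nrow(des$pair_truth))) {
    pr <- des$pair_truth[i, ]
    z <- mir_prof[pr$mirna_id, ]
    sdz <- stats::sd(z)
    z <- if (sdz > 0) (z - mean(z)) / sdz else z * 0
    s <- if (pr$sign == "negative") -1 else 1
    mu_gut[pr$gene_id, ] <- mu_gut[pr$gene_id, ] *
      2^(s * pr$beta * z[colnames(mu_gut)])
  }

  gut_mrna <- nb_draw(mu_gut, cfg$reps_mrna, cfg$dispersion,
                      cfg$depth_sdlog, "gut", "gut")
  liver_mrna <- nb_draw(des$mu_liver, cfg$reps_mrna, cfg$dispersion,
                        cfg$depth_sdlog, "liver", "liver")

  true_de_from_mu <- function(mu, min_lfc = 0.5) {
    lapply(stage_definitions(), function(cmp) {
      lfc <- log2((mu[, cmp[1]] + 0.5) / (mu[, cmp[2]] + 0.5))
      keep <- abs(lfc) > min_lfc
      data.frame(feature_id = rownames(mu)[keep], lfc = lfc[keep],
                 direction = ifelse(lfc[keep] > 0, "up", "down"),
                 row.names = NULL)
    })
  }

  truth <- list(
    stage_de_planted = list(gut = des$gut_plant, liver = des$liver_plant,
                            gut_mirna = des$mirna_plant),
    true_de = list(gut = true_de_from_mu(mu_gut),
                   liver = true_de_from_mu(des$mu_liver),
                   gut_mirna = true_de_from_mu(des$mu_mirna)),
    checkpoint_truth = list(gut = des$chk_gut, liver = des$chk_liver),
    pair_truth = des$pair_truth
  )
  list(gut_mrna = gut_mrna, liver_mrna = liver_mrna, gut_mirna = gut_mirna,
       truth = truth)
}

#' Simulate the immune library, gene sets and target map
#'
#' Builds the annotation inputs matching the planted design: an immune gene
#' library over the nine canonical processes containing the checkpoint
#' category pool (and, by default, the planted stage-DE genes grouped into
#' additional categories), a gene-set collection with one set per planted
#' pathway plus decoys, and a target map holding every planted coupling
#' plus random decoy pairs. Deterministic under the config seed.
#'
#' @param cfg A `sim_config`.
#' @return List with `library` (an `immune_library`), `gene_sets` (named
#'   list of gene vectors), `targets` (a `target_map`).
#' @export
simulate_library_and_sets <- function(cfg) {
  des <- sim_design(cfg)
  procs <- immune_process_labels()
  recs <- do.call(rbind, lapply(seq_along(des$cat_names), function(ci) {
    data.frame(gene_id = des$cat_members[[ci]],
               process = des$cat_process[ci],
               category = des$cat_names[ci])
  }))
  if (cfg$annotate_de_genes) {
    annotate <- function(plant, tag) {
      plant <- plant[order(plant$stage, -plant$lfc), ]
      n <- nrow(plant)
      chunk <- ceiling(seq_len(n) / cfg$genes_per_category)
      data.frame(gene_id = plant$feature_id,
                 process = procs[((chunk - 1) %% length(procs)) + 1],
                 category = sprintf("%s_DE%03d", tag, chunk))
    }
    recs <- rbind(recs, annotate(des$gut_plant, "G"),
                  annotate(des$liver_plant, "L"))
    # coupled miRNA targets get immune annotations too, so the immune
    # subnetwork and its stage-wise pair table are exercised
    n_t <- length(des$target_ids)
    chunk_t <- ceiling(seq_len(n_t) / cfg$genes_per_category)
    recs <- rbind(recs, data.frame(
      gene_id = des$target_ids,
      process = procs[((chunk_t - 1) %% length(procs)) + 1],
      category = sprintf("T_DE%03d", chunk_t)))
  }
  lib <- immune_library(recs)
  sets <- c(des$pathway_sets, des$decoy_sets)
  pairs <- rbind(des$pair_truth[c("mirna_id", "gene_id")], des$decoy_pairs)
  list(library = lib, gene_sets = sets,
       targets = target_map(pairs, source_tag = "synthetic"))
}

#' Default phenotype group parameters
#'
#' Per-diet-group means for the growth-record fields, shaped like a
#' three-diet trial (fish-meal control, 40\% and 70\% soybean-meal
#' substitution) over 49 days with 40 fish per cage and 3 cages per group.
#'
#' @return Data frame, one row per group.
#' @export
phenotype_group_defaults <- function() {
  data.frame(
    group = c("FM", "40SBM", "70SBM"),
    initial_weight = c(13.94, 13.83, 14.06),
    final_weight = c(51.04, 42.77, 26.73),
    feed_per_fish = c(59.68, 53.73, 34.93),
    fish_n_start = c(40L, 40L, 40L),
    fish_n_end = c(40L, 40L, 38L),
    days = c(49L, 49L, 49L),
    body_length = c(15.0, 14.5, 12.0),
    hi = c(3.18, 2.41, 2.14),
    ili = c(197.09, 189.69, 202.76),
    isi = c(4.74, 3.79, 3.18)
  )
}

#' Simulate phenotype records, density inputs and masks
#'
#' Growth records per group and cage around configurable group means with
#' multiplicative per-cage noise (`phenotype_noise_cv`; 0 reproduces the
#' means exactly), a toy immunofluorescence intensity image with known
#' signal and background values, and staining masks with configured
#' coverage.
#'
#' @param cfg A `sim_config`.
#' @param groups Group parameter table (defaults to
#'   [phenotype_group_defaults()]).
#' @param n_cages Cages per group (default 3).
#' @param mask_coverage Fraction of stained pixels in the generated masks
#'   (default 0.125 on a 16 x 16 grid).
#' @return List with `growth` (data frame of records), `density` (list with
#'   `intensity`, `signal_mask`, `background_rois`, `expected`), `masks`
#'   (list of logical matrices), `mask_coverage`.
#' @export
simulate_phenotype <- function(cfg, groups = phenotype_group_defaults(),
                               n_cages = 3, mask_coverage = 0.125) {
  set.seed(cfg$seed + 2L)
  cv <- cfg$phenotype_noise_cv
  noise <- function(mean, n) mean * (1 + cv * stats::rnorm(n))
  rows <- do.call(rbind, lapply(seq_len(nrow(groups)), function(gi) {
    g <- groups[gi, ]
    fw <- noise(g$final_weight, n_cages)
    bl <- noise(g$body_length, n_cages)
    data.frame(
      group = g$group, cage = seq_len(n_cages),
      initial_weight = noise(g$initial_weight, n_cages),
      final_weight = fw,
      feed_consumed = noise(g$feed_per_fish, n_cages) * g$fish_n_end,
      fish_n_start = g$fish_n_start, fish_n_end = g$fish_n_end,
      days = g$days,
      body_weight = fw, body_length = bl,
      hepatopancreas_weight = noise(g$hi, n_cages) / 100 * fw,
      intestine_weight = noise(g$isi, n_cages) / 100 * fw,
      intestine_length = noise(g$ili, n_cages) / 100 * bl
    )
  }))
  rownames(rows) <- NULL

  # toy density input: 4x4 image, 4 signal pixels of intensity 10, one
  # 4-pixel background region of intensity 2 -> mean density 2 by hand
  intensity <- matrix(0, 4, 4)
  signal_mask <- matrix(FALSE, 4, 4); signal_mask[1:4] <- TRUE
  intensity[signal_mask] <- 10
  roi <- matrix(FALSE, 4, 4); roi[13:16] <- TRUE
  intensity[roi] <- 2
  density <- list(intensity = intensity, signal_mask = signal_mask,
                  background_rois = list(roi),
                  expected = (4 * 10 - 2 * 4) / 16)

  side <- 16
  n_on <- round(mask_coverage * side * side)
  masks <- lapply(1:3, function(i) {
    m <- matrix(FALSE, side, side)
    m[sample.int(side * side, n_on)] <- TRUE
    m
  })
  list(growth = rows, density = density, masks = masks,
       mask_coverage = 100 * n_on / (side * side))
}

#' Simulate the full study
#'
#' Convenience wrapper bundling [simulate_counts()],
#' [simulate_library_and_sets()] and [simulate_phenotype()] for one config.
#'
#' @param cfg A `sim_config`.
#' @return List with all generator outputs plus `config`.
#' @export
simulate_study <- function(cfg) {
  counts <- simulate_counts(cfg)
  ann <- simulate_library_and_sets(cfg)
  phen <- simulate_phenotype(cfg)
  c(counts, ann, list(phenotype = phen, config = cfg))
}

#' Write every generated input to disk
#'
#' Writes the formats the analysis modules read: count TSVs with sample
#' sheets, the immune library TSV, gene sets as GMT, the target map TSV,
#' growth records TSV, mask TSVs, and the planted truth as JSON.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_sim_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(sim$gut_mrna, file.path(dir, "gut_mrna_counts.tsv"),
                     file.path(dir, "gut_mrna_samples.tsv"))
  write_count_matrix(sim$liver_mrna, file.path(dir, "liver_mrna_counts.tsv"),
                     file.path(dir, "liver_mrna_samples.tsv"))
  write_count_matrix(sim$gut_mirna, file.path(dir, "gut_mirna_counts.tsv"),
                     file.path(dir, "gut_mirna_samples.tsv"))
  write_immune_library(sim$library, file.path(dir, "immune_library.tsv"))
  write_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  utils::write.table(as.data.frame(sim$targets),
                     file.path(dir, "target_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$phenotype$growth, file.path(dir, "growth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_along(sim$phenotype$masks)) {
    utils::write.table(sim$phenotype$masks[[i]] * 1L,
                       file.path(dir, sprintf("mask_%d.tsv", i)),
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
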