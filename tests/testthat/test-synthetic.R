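test_that("the generator is deterministic under seed and sensitive to it", {
  cfg <- sim_config(9)
  a <- suppressMessages(simulate_counts(cfg))
  b <- suppressMessages(simulate_counts(cfg))
  expect_identical(a$gut_mrna$counts, b$gut_mrna$counts)
  expect_identical(a$gut_mirna$counts, b$gut_mirna$counts)
  expect_identical(a$truth, b$truth)
  c2 <- suppressMessages(simulate_counts(sim_config(10)))
  expect_false(identical(a$gut_mrna$counts, c2$gut_mrna$counts))

  # and through the file writers
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim_inputs(suppressMessages(simulate_study(cfg)), d1)
  write_sim_inputs(suppressMessages(simulate_study(cfg)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("generated counts match negative-binomial moments", {
  # 10,000 draws at fixed mu: empirical variance ~ mu + alpha mu^2
  cfg <- sim_config(11)
  mu <- matrix(100, nrow = 2500, ncol = 4,
               dimnames = list(sprintf("f%04d", 1:2500), trial_timepoints()))
  set.seed(cfg$seed)
  cm <- gutliveR:::nb_draw(mu, reps = 1, dispersion = 0.1, depth_sdlog = 0,
                           tissue = "gut", id_prefix = "x")
  draws <- as.vector(cm$counts)
  expect_length(draws, 10000)
  expect_equal(var(draws), 100 + 0.1 * 100^2, tolerance = 0.15)
  expect_equal(mean(draws), 100, tolerance = 0.05)
})

test_that("planted early genes show the planted fold change in the raw data", {
  ratios <- c()
  for (sd in c(12, 13, 14)) {
    sim <- suppressMessages(simulate_counts(sim_config(sd)))
    cm <- sim$gut_mrna
    sf <- size_factors(cm$counts, pseudo_reference = TRUE)
    norm <- sweep(cm$counts, 2, sf, "/")
    pl <- sim$truth$stage_de_planted$gut
    up_early <- pl$feature_id[pl$stage == "early" & pl$lfc > 0]
    m0 <- rowMeans(norm[up_early, cm$samples$timepoint == "0d"])
    m3 <- rowMeans(norm[up_early, cm$samples$timepoint == "3w"])
    ratios <- c(ratios, m3 / m0)
  }
  expect_gte(mean(ratios), 3.2)
  expect_lte(mean(ratios), 5.0)
})

test_that("a null configuration has exchangeable time points", {
  cfg <- sim_config(15, n_de_per_stage = 0, n_mirna_de_per_stage = 0,
                    n_coupled_pairs = 0, n_checkpoint_categories = 0,
                    annotate_de_genes = FALSE)
  sim <- suppressMessages(simulate_counts(cfg))
  de <- stage_de(sim$gut_mrna)
  for (s in names(de)) {
    n_calls <- length(c(de[[s]]$up_set, de[[s]]$down_set))
    expect_lte(n_calls, 0.05 * nrow(sim$gut_mrna$counts))
  }
})

test_that("the generated library matches the configured arithmetic", {
  # 45 categories x 4 genes spanning all nine processes: 180 records
  cfg <- sim_config(16, n_checkpoint_categories = 45, genes_per_category = 4,
                    annotate_de_genes = FALSE)
  ann <- simulate_library_and_sets(cfg)
  expect_equal(nrow(ann$library$records), 180)
  expect_setequal(unique(ann$library$records$process),
                  immune_process_labels())

  # planted pairs are all present in the target map
  sim_cfg <- sim_config(16)
  ann2 <- simulate_library_and_sets(sim_cfg)
  sim <- suppressMessages(simulate_counts(sim_cfg))
  tm_keys <- paste(ann2$targets$mirna_id, ann2$targets$gene_id)
  expect_true(all(paste(sim$truth$pair_truth$mirna_id,
                        sim$truth$pair_truth$gene_id) %in% tm_keys))
})

test_that("a planted pathway enriches against the simulated universe", {
  cfg <- sim_config(17)
  ann <- simulate_library_and_sets(cfg)
  sim <- suppressMessages(simulate_counts(cfg))
  universe <- rownames(sim$gut_mrna$counts)
  coll <- gene_set_collection(ann$gene_sets, universe)
  pl <- sim$truth$stage_de_planted$gut
  de_early <- pl$feature_id[pl$stage == "early"]
  tab <- enrich(de_early, coll)
  expect_lt(tab$q[tab$set_id == "planted_early"], 0.05)
})

test_that("phenotype generation honours configured means and masks", {
  cfg0 <- sim_config(18, phenotype_noise_cv = 0)
  phen <- simulate_phenotype(cfg0)
  defaults <- phenotype_group_defaults()
  fm <- phen$growth[phen$growth$group == "FM", ]
  expect_true(all(fm$final_weight == defaults$final_weight[1]))
  met <- growth_metrics(as.list(fm[1, -(1:2)]))
  expect_equal(unname(met["survival"]), 100)
  expect_equal(unname(met["HI"]), defaults$hi[1], tolerance = 1e-10)

  sbm70 <- phen$growth[phen$growth$group == "70SBM", ]
  expect_equal(unname(growth_metrics(as.list(sbm70[1, -(1:2)]))["survival"]),
               95)

  # Table-2-like group means separate under the growth alpha
  cfg <- sim_config(18)
  phen2 <- simulate_phenotype(cfg)
  wg <- function(g) {
    rows <- phen2$growth[phen2$growth$group == g, ]
    apply(rows, 1, function(r)
      growth_metrics(as.list(r)[-(1:2)])["WG"])
  }
  cmp <- group_compare(wg("FM"), wg("70SBM"), alpha = 0.05)
  expect_true(cmp$significant)

  # masks carry the configured coverage exactly
  for (m in phen$masks) expect_equal(percent_area(m), 12.5)
  expect_equal(phen$mask_coverage, 12.5)

  # the packaged density example evaluates to its constructed value
  expect_equal(mean_density(phen$density$intensity, phen$density$signal_mask,
                            phen$density$background_rois),
               phen$density$expected)
})
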