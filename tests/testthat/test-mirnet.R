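test_that("target maps deduplicate and validate", {
  tm <- target_map(data.frame(
    mirna_id = c("m1", "m1", "m2"),
    gene_id = c("g1", "g1", "g2")))
  expect_equal(nrow(tm), 2)
  expect_error(target_map(data.frame(mirna_id = "", gene_id = "g1")),
               "empty identifier")
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(as.data.frame(tm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_equal(nrow(read_target_map(path)), 2)
})

test_that("pair correlations reproduce hand-computed Pearson values", {
  # log2(count + 1) profiles: mirna (1,2,3,4); genes as annotated
  mir_cm <- profile_count_matrix(list(m1 = c(1, 2, 3, 4)), reps = 2)
  mrna_cm <- profile_count_matrix(list(
    identical = c(1, 2, 3, 4),   # r = 1
    anti = c(4, 3, 2, 1),        # affine decreasing: r = -1
    jumbled = c(2, 1, 4, 3),     # hand Pearson: r = 0.6
    flat = c(3, 3, 3, 3)         # undefined, dropped
  ), reps = 3)
  tm <- target_map(data.frame(
    mirna_id = "m1",
    gene_id = c("identical", "anti", "jumbled", "flat")))
  res <- suppressMessages(pair_correlations(mir_cm, mrna_cm, tm))
  expect_equal(nrow(res), 3)
  expect_equal(res$r[res$gene_id == "identical"], 1)
  expect_equal(res$r[res$gene_id == "anti"], -1)
  expect_equal(res$r[res$gene_id == "jumbled"], 0.6)
  expect_true(all(abs(res$r) <= 1))
  expect_true(all(res$n_points == 4))
  expect_message(pair_correlations(mir_cm, mrna_cm, tm), "flat")
})

test_that("stage networks join target pairs with DE calls by hand enumeration", {
  corr <- data.frame(
    mirna_id = c("m1", "m1", "m2", "m3"),
    gene_id = c("gA", "gB", "gC", "gA"),
    r = c(-0.9, 0.8, -0.5, 0.7), n_points = 4)
  mirna_de <- list(up_set = "m1", down_set = "m2")
  mrna_de <- list(up_set = c("gB", "gC"), down_set = "gA")
  net <- stage_network(corr, mirna_de, mrna_de, "early")
  # m3 is not DE: its pair is excluded; the 3 remaining connect DE nodes
  expect_equal(nrow(net), 3)
  expect_false("m3" %in% net$mirna_id)
  e1 <- net[net$mirna_id == "m1" & net$gene_id == "gA", ]
  expect_equal(e1$mirna_dir, "up")
  expect_equal(e1$gene_dir, "down")
  expect_equal(e1$sign, "negative")
  e2 <- net[net$mirna_id == "m2", ]
  expect_equal(e2$mirna_dir, "down")
  expect_equal(e2$sign, "negative")
  expect_true(all(net$stage == "early"))

  # empty DE sets: empty network
  empty <- stage_network(corr, list(up_set = character(0), down_set = character(0)),
                         mrna_de, "late")
  expect_equal(nrow(empty), 0)
})

test_that("the immune filter keeps only library targets and summarizes them", {
  corr <- data.frame(
    mirna_id = c("m1", "m1", "m2"),
    gene_id = c("g1", "gZ", "g3"), r = c(-0.9, 0.8, -0.5), n_points = 4)
  net <- stage_network(corr,
                       list(up_set = c("m1", "m2"), down_set = character(0)),
                       list(up_set = c("g1", "gZ"), down_set = "g3"),
                       "middle")
  imm <- immune_subnetwork(net, toy_library())
  expect_equal(sort(unique(imm$edges$gene_id)), c("g1", "g3"))
  expect_true(all(imm$edges$immune))
  expect_equal(unique(imm$summary$process), "complement system")
  expect_true(any(grepl("m1 \\(g1\\)", imm$summary$mirna_targets)))
  expect_true(all(imm$summary$n_genes >= 1))

  # no immune targets: empty result
  none <- immune_subnetwork(net[net$gene_id == "gZ", ], toy_library())
  expect_equal(nrow(none$edges), 0)
  expect_equal(nrow(none$summary), 0)
})

test_that("network export writes SIF/TSV/GraphML and round-trips", {
  corr <- data.frame(
    mirna_id = c("m1", "m2", "m2"),
    gene_id = c("gA", "gA", "gB"), r = c(-0.9, 0.5, 0.7), n_points = 4)
  net <- stage_network(corr,
                       list(up_set = "m1", down_set = "m2"),
                       list(up_set = "gB", down_set = "gA"), "early")
  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- export_network(net, prefix)
  expect_true(all(file.exists(paths)))
  sif <- readLines(paste0(prefix, ".sif"))
  expect_length(sif, 3)
  nodes <- utils::read.delim(paste0(prefix, "_nodes.tsv"))
  expect_lte(nrow(nodes), 5)
  expect_true(all(nodes$regulation %in% c("up", "down")))
  back <- import_network(paste0(prefix, ".graphml"))
  expect_equal(nrow(back), 3)
  expect_setequal(paste(back$mirna_id, back$gene_id),
                  paste(net$mirna_id, net$gene_id))
  expect_setequal(back$sign, net$sign)

  # empty network still writes valid files
  empty <- net[0, ]
  paths0 <- export_network(empty, file.path(withr::local_tempdir(), "none"))
  expect_true(all(file.exists(paths0)))
  expect_equal(nrow(import_network(paths0[4])), 0)
})

test_that("emitted edges are always a subset of the target map", {
  cfg <- sim_config(30)
  sim <- suppressMessages(simulate_study(cfg))
  corr <- suppressMessages(
    pair_correlations(sim$gut_mirna, sim$gut_mrna, sim$targets))
  de_mir <- suppressWarnings(stage_de(sim$gut_mirna))
  de_g <- stage_de(sim$gut_mrna)
  tm_keys <- paste(sim$targets$mirna_id, sim$targets$gene_id)
  for (s in c("early", "middle", "late")) {
    net <- stage_network(corr, de_mir[[s]], de_g[[s]], s)
    expect_true(all(paste(net$mirna_id, net$gene_id) %in% tm_keys))
    expect_true(all(abs(net$r) <= 1))
  }
})

test_that("decoy pairs correlate less than planted couplings", {
  cfg <- sim_config(30)
  sim <- suppressMessages(simulate_study(cfg))
  corr <- suppressMessages(
    pair_correlations(sim$gut_mirna, sim$gut_mrna, sim$targets))
  key <- paste(corr$mirna_id, corr$gene_id)
  planted <- key %in% paste(sim$truth$pair_truth$mirna_id,
                            sim$truth$pair_truth$gene_id)
  expect_gt(median(abs(corr$r[planted])), median(abs(corr$r[!planted])))
})
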