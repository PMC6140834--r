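# builds a category_tests object directly from a padj table, for rule tests
fake_tests <- function(padj_by_cmp, alpha = 0.05) {
  cats <- rownames(padj_by_cmp)
  info <- data.frame(process = rep("complement system", length(cats)),
                     category = cats,
                     n_genes = 1, member_gene_ids = "gX")
  tests <- do.call(rbind, lapply(colnames(padj_by_cmp), function(cmp) {
    data.frame(process = info$process, category = info$category,
               comparison = cmp, p = padj_by_cmp[, cmp],
               padj = padj_by_cmp[, cmp])
  }))
  structure(list(tests = tests, info = info, alpha = alpha),
            class = "category_tests")
}

test_that("category profiles equal brute-force group-by means", {
  set.seed(71)
  cnt <- matrix(rnbinom(30 * 12, mu = 100, size = 10), nrow = 30,
                dimnames = list(sprintf("g%02d", 1:30), NULL))
  cm <- toy_count_matrix(cnt)
  lib <- immune_library(data.frame(
    gene_id = sprintf("g%02d", 1:12),
    process = rep(immune_process_labels()[1:3], each = 4),
    category = rep(c("c1", "c2", "c3"), each = 4)
  ))
  prof <- category_profile(cm, lib)
  expect_equal(nrow(prof$profile), 3)

  sf <- size_factors(cm$counts, pseudo_reference = TRUE)
  logn <- log2(sweep(cm$counts, 2, sf, "/") + 1)
  for (i in 1:3) {
    members <- sprintf("g%02d", (i - 1) * 4 + 1:4)
    expect_equal(unname(prof$profile[i, ]), unname(colMeans(logn[members, ])))
  }

  # single-member category equals that gene's log2 normalized value
  lib1 <- immune_library(data.frame(gene_id = "g01",
                                    process = "pattern recognition",
                                    category = "solo"))
  prof1 <- category_profile(cm, lib1)
  expect_equal(unname(prof1$profile[1, ]), unname(logn["g01", ]))

  # categories without expressed members are dropped with a message
  lib2 <- immune_library(data.frame(
    gene_id = c("g01", "absent"),
    process = rep("complement system", 2),
    category = c("c1", "ghost")
  ))
  expect_message(category_profile(cm, lib2), "dropped")
})

test_that("category t-tests handle degenerate and strong-signal cases", {
  tps <- trial_timepoints()
  sheet <- data.frame(sample_id = paste0("s", 1:12), tissue = "gut",
                      timepoint = rep(tps, each = 3), replicate = rep(1:3, 4))
  prof_mat <- rbind(
    flat = rep(5, 12),
    jump = c(rep(0, 3), 10, 10.1, 9.9, rep(0, 6))
  )
  prof <- structure(list(
    profile = prof_mat,
    info = data.frame(process = rep("complement system", 2),
                      category = c("flat", "jump"), n_genes = 1,
                      member_gene_ids = c("a", "b")),
    samples = sheet), class = "category_profile")
  res <- category_tests(prof, list(`3w_vs_0d` = c("3w", "0d")))
  expect_equal(res$tests$p[res$tests$category == "flat"], 1)
  expect_lt(res$tests$p[res$tests$category == "jump"], 1e-4)

  expect_error(
    category_tests(structure(list(profile = prof_mat[, 1:4, drop = FALSE],
                                  info = prof$info,
                                  samples = sheet[c(1, 4, 7, 10), ]),
                             class = "category_profile"),
                   list(`3w_vs_0d` = c("3w", "0d"))),
    ">= 2 replicates")
})

test_that("the checkpoint rules follow the printed clauses", {
  gut_cmp <- c("7w_vs_5w", "7w_vs_3w", "7w_vs_0d")
  m <- matrix(1, nrow = 4, ncol = 3, dimnames = list(
    c("none", "restored", "still_changed", "via_3w"), gut_cmp))
  m["restored", ] <- c(0.01, 0.8, 0.50)       # perturbed then back: selected
  m["still_changed", ] <- c(0.01, 0.8, 0.01)  # still away from baseline: not
  m["via_3w", ] <- c(0.9, 0.02, 0.60)         # via the 7w-vs-3w clause
  chk <- select_checkpoints(fake_tests(m), "gut")
  expect_equal(chk$category[chk$selected], c("restored", "via_3w"))

  # all padj = 1: nothing selected in either tissue
  chk0 <- select_checkpoints(fake_tests(matrix(
    1, 2, 3, dimnames = list(c("a", "b"), gut_cmp))), "gut")
  expect_false(any(chk0$selected))

  liver_cmp <- c("3w_vs_0d", "5w_vs_0d", "7w_vs_0d")
  ml <- matrix(1, nrow = 2, ncol = 3,
               dimnames = list(c("quiet", "shifted"), liver_cmp))
  ml["shifted", "5w_vs_0d"] <- 0.001
  chk_l <- select_checkpoints(fake_tests(ml), "liver")
  expect_equal(chk_l$category[chk_l$selected], "shifted")

  # missing comparison is named in the error
  expect_error(select_checkpoints(fake_tests(m[, 1:2]), "gut"), "7w_vs_0d")

  # gut-selected categories never have padj(7w vs 0d) < alpha
  set.seed(72)
  for (i in 1:25) {
    r <- matrix(runif(30), nrow = 10, ncol = 3,
                dimnames = list(paste0("c", 1:10), gut_cmp))
    res <- select_checkpoints(fake_tests(r), "gut")
    expect_false(any(res$selected & res[["padj_7w_vs_0d"]] < 0.05))
  }

  # permuting categories permutes rows only
  perm <- c(3, 1, 4, 2)
  chk_p <- select_checkpoints(fake_tests(m[perm, ]), "gut")
  reord <- chk_p[match(chk$category, chk_p$category), ]
  rownames(reord) <- NULL
  expect_equal(reord$selected, chk$selected)
})

test_that("planted gut checkpoint categories are recovered from counts", {
  cfg <- sim_config(77, annotate_de_genes = FALSE)
  sim <- suppressMessages(simulate_study(cfg))
  prof <- suppressMessages(category_profile(sim$gut_mrna, sim$library))
  expect_equal(nrow(prof$profile), 40)
  tst <- category_tests(prof, checkpoint_comparisons("gut"))
  chk <- select_checkpoints(tst, "gut")
  sel <- chk$category[chk$selected]
  truth <- sim$truth$checkpoint_truth$gut
  expect_gte(sum(truth %in% sel), 4)
  expect_lte(sum(!(sel %in% truth)), 1)
})
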