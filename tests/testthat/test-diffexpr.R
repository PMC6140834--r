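test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10, 20, 30, 40), ncol = 2, byrow = FALSE,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  m[, 2] <- m[, 1]
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(A = c(10, 20, 5, 80), B = 2 * c(10, 20, 5, 80))
  sf <- size_factors(m2)
  expect_equal(unname(sf["B"] / sf["A"]), 2)

  # brute-force oracle on a 4 x 3 toy
  toy <- matrix(c(10, 4, 100, 7,
                  20, 2, 150, 7,
                  15, 8, 50, 14), ncol = 3,
                dimnames = list(letters[1:4], c("s1", "s2", "s3")))
  geo <- apply(toy, 1, function(x) exp(mean(log(x))))
  raw <- apply(toy, 2, function(col) median(col / geo))
  expected <- raw / exp(mean(log(raw)))
  expect_equal(unname(size_factors(toy)), unname(expected))

  # invariant to feature permutation
  set.seed(5)
  perm <- sample(nrow(toy))
  expect_equal(size_factors(toy[perm, ]), size_factors(toy))

  # equivariant to global column scaling
  sc <- c(1, 2.5, 0.4)
  sf_scaled <- size_factors(sweep(toy, 2, sc, "*"))
  expect_equal(unname(sf_scaled / size_factors(toy)),
               unname(sc / exp(mean(log(sc)))))

  # geometric mean of factors is 1
  expect_equal(exp(mean(log(size_factors(toy)))), 1)

  all_zero_row <- rbind(c(0, 5, 3), c(4, 0, 1))
  expect_error(size_factors(all_zero_row), "pseudo_reference")
  expect_length(size_factors(all_zero_row, pseudo_reference = TRUE), 3)
})

test_that("dispersion estimation matches the NB moment relation", {
  # constant feature: variance 0 -> floored (raw estimator)
  cnt <- rbind(rep(50, 6), c(10, 60, 30, 20, 80, 40))
  disp <- estimate_dispersion(cnt, rep(c("A", "B"), each = 3),
                              sf = rep(1, 6), moderate = FALSE)
  expect_equal(unname(disp[1]), 1e-8)

  # Poisson data: alpha ~ 0
  set.seed(31)
  pois <- matrix(rpois(500 * 200, 50), nrow = 500)
  d <- estimate_dispersion(pois, rep("A", 200), sf = rep(1, 200),
                           moderate = FALSE)
  expect_lte(median(d), 0.02)

  # NB alpha = 0.5: within 20% for most features at n = 200
  set.seed(32)
  nb <- matrix(rnbinom(500 * 200, mu = 100, size = 2), nrow = 500)
  d <- estimate_dispersion(nb, rep("A", 200), sf = rep(1, 200),
                           moderate = FALSE)
  expect_gte(mean(abs(d - 0.5) / 0.5 <= 0.2), 0.8)

  # moderation pulls extremes toward the centre without moving it much
  dm <- estimate_dispersion(nb, rep("A", 200), sf = rep(1, 200))
  expect_lt(sd(dm), sd(d))
  expect_equal(median(dm), median(d), tolerance = 0.05)
  expect_equal(attr(dm, "df"), attr(d, "df") + 8)
})

test_that("the NB Wald test recovers planted fold changes and is symmetric", {
  set.seed(21)
  ca <- matrix(rnbinom(500 * 3, mu = 100, size = 20), 500)
  cb <- matrix(rnbinom(500 * 3, mu = 400, size = 20), 500)
  disp <- estimate_dispersion(cbind(ca, cb), rep(c("A", "B"), each = 3),
                              sf = rep(1, 6))
  res <- nb_wald(ca, cb, rep(1, 3), rep(1, 3), disp)
  expect_equal(median(res$log2FC), 2, tolerance = 0.3 / 2)
  expect_true(all(res$p >= 0 & res$p <= 1))

  swapped <- nb_wald(cb, ca, rep(1, 3), rep(1, 3), disp)
  expect_equal(swapped$log2FC, -res$log2FC)
  expect_equal(swapped$p, res$p)

  # identical group means at large n: tiny fold changes
  set.seed(22)
  big_a <- matrix(rnbinom(200 * 150, mu = 200, size = 10), 200)
  big_b <- matrix(rnbinom(200 * 150, mu = 200, size = 10), 200)
  disp_b <- estimate_dispersion(cbind(big_a, big_b),
                                rep(c("A", "B"), each = 150),
                                sf = rep(1, 300))
  null_res <- nb_wald(big_a, big_b, rep(1, 150), rep(1, 150), disp_b)
  expect_lte(max(abs(null_res$log2FC)), 0.25)
  expect_lte(median(abs(null_res$log2FC)), 0.1)

  # all-zero features are flagged, not tested
  z <- nb_wald(matrix(0, 2, 3), matrix(0, 2, 3), rep(1, 3), rep(1, 3),
               c(0.1, 0.1))
  expect_equal(z$log2FC, c(0, 0))
  expect_equal(z$p, c(1, 1))
  expect_true(all(z$all_zero))
})

test_that("null NB data yields a calibrated raw p-value fraction", {
  set.seed(11)
  mu <- rlnorm(2000, log(100), 1)
  cnt <- matrix(rnbinom(2000 * 6, mu = rep(mu, 6), size = 10), nrow = 2000)
  sf <- size_factors(cnt, pseudo_reference = TRUE)
  disp <- estimate_dispersion(cnt, rep(c("A", "B"), each = 3), sf = sf)
  res <- nb_wald(cnt[, 1:3], cnt[, 4:6], sf[1:3], sf[4:6], disp)
  expect_gte(mean(res$p < 0.05), 0.03)
  expect_lte(mean(res$p < 0.05), 0.08)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(41)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, brute_force_bh(p))
    expect_true(all(adj >= p - 1e-15 & adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
})

test_that("stage_de tests the three consecutive contrasts and validates input", {
  set.seed(51)
  cnt <- matrix(rnbinom(50 * 12, mu = 100, size = 10), nrow = 50)
  cm <- toy_count_matrix(cnt)
  de <- stage_de(cm)
  expect_named(de, c("early", "middle", "late"))
  expect_equal(de$early$comparison, c("3w", "0d"))
  expect_equal(de$middle$comparison, c("5w", "3w"))
  expect_equal(de$late$comparison, c("7w", "5w"))
  for (s in names(de)) {
    tab <- de[[s]]$table
    expect_true(all(tab$padj >= tab$p - 1e-15, na.rm = TRUE))
    expect_length(intersect(de[[s]]$up_set, de[[s]]$down_set), 0)
    calls <- tab$call[tab$padj < 0.05 & !is.na(tab$padj)]
    expect_true(all(calls %in% c("up", "down")))
  }

  # missing time point is an informative error
  cm_missing <- cm
  cm_missing$samples$timepoint[cm_missing$samples$timepoint == "7w"] <- "5w"
  expect_error(stage_de(cm_missing), "7w")

  # two replicates triggers the low-power warning
  cnt2 <- matrix(rnbinom(30 * 8, mu = 100, size = 10), nrow = 30)
  expect_warning(stage_de(toy_count_matrix(cnt2, reps = 2)), "power")

  # all-pairs mode adds the extra contrasts
  de_all <- stage_de(cm, all_pairs = TRUE)
  expect_true(all(c("5w_vs_0d", "7w_vs_0d", "7w_vs_3w") %in% names(de_all)))
})

test_that("stage results write and re-read as TSV", {
  set.seed(52)
  cnt <- matrix(rnbinom(30 * 12, mu = 100, size = 10), nrow = 30)
  de <- stage_de(toy_count_matrix(cnt))
  dir <- withr::local_tempdir()
  paths <- write_stage_de(de, dir, "toy_")
  expect_true(all(file.exists(paths)))
  back <- utils::read.delim(paths[["early"]])
  expect_equal(back$feature_id, de$early$table$feature_id)
  expect_equal(back$log2FC, de$early$table$log2FC)
})

test_that("count matrices round-trip through TSV", {
  set.seed(53)
  cnt <- matrix(rnbinom(20 * 12, mu = 50, size = 5), nrow = 20,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
  cm <- toy_count_matrix(cnt)
  cp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(cm, cp, sp)
  cm2 <- read_count_matrix(cp, sp)
  expect_equal(cm2$counts, cm$counts)
  expect_equal(cm2$samples$timepoint, cm$samples$timepoint)
})
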