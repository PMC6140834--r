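#' Canonical time points of the feeding trial
#' @return `c("0d", "3w", "5w", "7w")`
#' @export
trial_timepoints <- function() c("0d", "3w", "5w", "7w")

#' Stage definitions: consecutive-time-point contrasts
#'
#' The three stages of the 7-week trial compare consecutive time points:
#' early = 3w vs 0d, middle = 5w vs 3w, late = 7w vs 5w. In each contrast
#' the later time point is the numerator of the fold change.
#'
#' @return Named list of `c(later, earlier)` time-point pairs.
#' @export
stage_definitions <- function() {
  list(
    early  = c("3w", "0d"),
    middle = c("5w", "3w"),
    late   = c("7w", "5w")
  )
}

#' Construct a count matrix with its sample sheet
#'
#' @param counts Integer matrix, features x samples, non-negative. Row names
#'   are feature ids; column names are sample ids.
#' @param sample_sheet Data frame with columns `sample_id`, `tissue`
#'   (`"gut"` or `"liver"`), `timepoint`, `replicate`; rows in the same
#'   order as the count columns.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, sample_sheet) {
  counts <- as.matrix(counts)
  stopifnot(is.numeric(counts))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  needed <- c("sample_id", "tissue", "timepoint", "replicate")
  missing_cols <- setdiff(needed, names(sample_sheet))
  if (length(missing_cols)) {
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(sample_sheet) != ncol(counts)) {
    stop("sample sheet has ", nrow(sample_sheet), " rows but counts has ",
         ncol(counts), " columns")
  }
  if (anyDuplicated(sample_sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet")
  }
  if (!all(sample_sheet$tissue %in% c("gut", "liver"))) {
    stop("tissue must be 'gut' or 'liver'")
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sample_sheet$sample_id
  } else if (!identical(colnames(counts), as.character(sample_sheet$sample_id))) {
    stop("count column names do not match sample sheet order")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("feature_%05d", seq_len(nrow(counts)))
  }
  sample_sheet$replicate <- as.integer(sample_sheet$replicate)
  if (any(sample_sheet$replicate < 1)) stop("replicate must be positive")
  structure(list(counts = counts, samples = sample_sheet),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Count matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  print(table(x$samples$tissue, x$samples$timepoint))
  invisible(x)
}

#' Read a count matrix and sample sheet from TSV files
#'
#' The counts file has a `feature_id` first column and one column per
#' sample; the sample sheet is a TSV with columns `sample_id`, `tissue`,
#' `timepoint`, `replicate`.
#'
#' @param counts_path,samples_path File paths.
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  tab <- utils::read.delim(counts_path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  sheet <- utils::read.delim(samples_path, sep = "\t", header = TRUE,
                             colClasses = "character", quote = "")
  sheet$replicate <- as.integer(sheet$replicate)
  count_matrix(m, sheet)
}

#' Write a count matrix and its sample sheet to TSV files
#' @param cm A `count_matrix`.
#' @param counts_path,samples_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_count_matrix <- function(cm, counts_path, samples_path) {
  stopifnot(inherits(cm, "count_matrix"))
  out <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(out, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cm$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, samples_path))
}

#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed as the median across features of the
#' ratio of each count to the feature's geometric mean, using only features
#' with no zero count as the reference set; the factors are then rescaled
#' to have geometric mean 1.
#'
#' @param counts Count matrix (features x samples) or a `count_matrix`.
#' @param pseudo_reference If `TRUE`, fall back to geometric means over
#'   positive counts only when no zero-free feature exists.
#' @return Positive numeric vector, one factor per sample, geometric mean 1.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  zero_free <- rowSums(counts == 0) == 0
  if (!any(zero_free)) {
    if (!pseudo_reference) {
      stop("no feature has all-positive counts; rerun with ",
           "pseudo_reference = TRUE to use positive-count geometric means")
    }
    logref <- apply(counts, 1, function(x) {
      pos <- x > 0
      if (!any(pos)) return(NA_real_)
      mean(log(x[pos]))
    })
    use <- is.finite(logref)
  } else {
    logref <- rowMeans(log(counts))
    logref[!zero_free] <- NA_real_
    use <- zero_free
  }
  if (!any(use)) stop("no usable reference features for size factors")
  ratios <- counts[use, , drop = FALSE] / exp(logref[use])
  sf <- apply(ratios, 2, function(r) {
    stats::median(r[is.finite(r) & r > 0])
  })
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Moderated method-of-moments negative-binomial dispersion
#'
#' Per-feature dispersion `alpha` in the NB parameterization
#' `Var = mu + alpha * mu^2`, estimated on normalized counts by pooling the
#' moment estimate `(s^2 - mu) / mu^2` across replicate groups (weighted by
#' degrees of freedom) and floored at `floor`. With few replicates the raw
#' per-feature estimate is very noisy, so by default it is moderated
#' empirical-Bayes style: shrunk toward the cross-feature median with
#' `prior_df` pseudo-degrees of freedom,
#' `alpha_mod = (d * alpha_hat + prior_df * median(alpha_hat)) / (d + prior_df)`
#' with `d` the pooled residual degrees of freedom. The `"df"` attribute of
#' the result (`d + prior_df` when moderated, else `d`) feeds the t
#' reference of [nb_wald()].
#'
#' @param counts Raw count matrix (features x samples).
#' @param groups Factor/vector of group labels, one per sample; each group
#'   used must have >= 2 replicates.
#' @param sf Size factors (defaults to [size_factors()] of `counts`).
#' @param floor Lower bound for the dispersion (default `1e-8`).
#' @param moderate Shrink toward the cross-feature median (default `TRUE`).
#' @param prior_df Moderation strength in pseudo-degrees of freedom
#'   (default 8).
#' @return Numeric vector of dispersions, one per feature, with a `"df"`
#'   attribute.
#' @export
estimate_dispersion <- function(counts, groups, sf = NULL, floor = 1e-8,
                                moderate = TRUE, prior_df = 8) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(counts))
  if (is.null(sf)) sf <- size_factors(counts, pseudo_reference = TRUE)
  norm <- sweep(counts, 2, sf, "/")
  num <- rep(0, nrow(counts))
  den <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    n <- length(idx)
    if (n < 2) next
    mu <- rowMeans(norm[, idx, drop = FALSE])
    s2 <- apply(norm[, idx, drop = FALSE], 1, stats::var)
    a <- ifelse(mu > 0, (s2 - mu) / mu^2, 0)
    num <- num + (n - 1) * a
    den <- den + (n - 1)
  }
  if (den == 0) stop("every group needs >= 2 replicates to estimate dispersion")
  alpha <- pmax(floor, num / den)
  df <- den
  if (moderate && length(alpha) > 1) {
    center <- stats::median(alpha)
    alpha <- pmax(floor, (den * alpha + prior_df * center) / (den + prior_df))
    df <- den + prior_df
  }
  names(alpha) <- rownames(counts)
  attr(alpha, "df") <- df
  alpha
}

#' Negative-binomial Wald test between two sample groups
#'
#' For each feature, the log2 fold change is
#' `log2((mean_B + c) / (mean_A + c))` on normalized counts with pseudocount
#' `c = 0.5`; its standard error follows from the NB variance
#' `mu/s_j + alpha * mu^2` of each normalized count by the delta method, and
#' a two-sided p-value is taken from the t distribution with `df` degrees
#' of freedom — by default the residual degrees of freedom behind the
#' dispersion estimate (its `"df"` attribute when present, else
#' `n_A + n_B - 2`). A small-sample t reference is used because at the
#' replicate numbers of this design the asymptotic normal reference is
#' anti-conservative.
#'
#' Features with zero counts in every sample of both groups are reported
#' with `log2FC = 0`, `p = 1` and flagged `all_zero`.
#'
#' @param counts_a,counts_b Raw count matrices for the two groups (same
#'   features, in the same order). Group A is the reference (denominator).
#' @param sf_a,sf_b Size factors for the columns of each group.
#' @param dispersion Per-feature NB dispersion vector.
#' @param pseudocount Stabilizing constant added to both group means
#'   (default 0.5).
#' @param df Degrees of freedom of the t reference; defaults to the
#'   dispersion estimate's `"df"` attribute, else `n_A + n_B - 2`.
#' @return Data frame with `feature_id`, `baseMean`, `log2FC`, `SE`, `stat`,
#'   `p`, `all_zero`.
#' @export
nb_wald <- function(counts_a, counts_b, sf_a, sf_b, dispersion,
                    pseudocount = 0.5, df = NULL) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  stopifnot(nrow(counts_a) == nrow(counts_b),
            ncol(counts_a) == length(sf_a),
            ncol(counts_b) == length(sf_b),
            ncol(counts_a) >= 1, ncol(counts_b) >= 1)
  alpha <- rep_len(dispersion, nrow(counts_a))
  norm_a <- sweep(counts_a, 2, sf_a, "/")
  norm_b <- sweep(counts_b, 2, sf_b, "/")
  mu_a <- rowMeans(norm_a); mu_b <- rowMeans(norm_b)
  n_a <- ncol(counts_a); n_b <- ncol(counts_b)

  lfc <- log2((mu_b + pseudocount) / (mu_a + pseudocount))

  # Var(K_ij / s_j) = mu/s_j + alpha*mu^2 for NB counts; variance of the
  # group mean then maps to the log2 scale via the delta method.
  var_mean_a <- (mu_a * sum(1 / sf_a) + n_a * alpha * mu_a^2) / n_a^2
  var_mean_b <- (mu_b * sum(1 / sf_b) + n_b * alpha * mu_b^2) / n_b^2
  se <- sqrt(var_mean_a / (mu_a + pseudocount)^2 +
             var_mean_b / (mu_b + pseudocount)^2) / log(2)

  all_zero <- mu_a == 0 & mu_b == 0
  stat <- ifelse(se > 0, lfc / se, 0)
  if (is.null(df)) {
    df <- attr(dispersion, "df")
    if (is.null(df)) df <- n_a + n_b - 2
  }
  df <- max(1, df)
  p <- 2 * stats::pt(abs(stat), df = df, lower.tail = FALSE)
  lfc[all_zero] <- 0
  stat[all_zero] <- 0
  p[all_zero] <- 1
  se[all_zero] <- 0

  data.frame(
    feature_id = if (!is.null(rownames(counts_a))) rownames(counts_a)
                 else sprintf("feature_%05d", seq_along(lfc)),
    baseMean = (mu_a + mu_b) / 2,
    log2FC = lfc, SE = se, stat = stat, p = pmin(1, p),
    all_zero = all_zero,
    row.names = NULL
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up BH adjustment with enforced monotonicity, mapped back to
#' the input order. Inputs outside `[0, 1]` are an error.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Stage-wise differential expression
#'
#' Runs the NB Wald test for each consecutive-time-point contrast (early =
#' 3w vs 0d, middle = 5w vs 3w, late = 7w vs 5w), applying BH adjustment
#' within each contrast across all tested features and calling features
#' with adjusted p below `alpha` as up- or down-regulated by the sign of the
#' fold change. Size factors are computed once on the full matrix;
#' dispersions are pooled across the time-point replicate groups. Features
#' with zero counts in all samples of a contrast are excluded from that
#' contrast before BH (their rows are reported with `call = "ns"` and
#' `padj = NA`).
#'
#' @param cm A `count_matrix` containing the four canonical time points for
#'   one tissue.
#' @param alpha Adjusted-p calling threshold (default 0.05).
#' @param all_pairs If `TRUE`, additionally test every time-point pair (for
#'   time-point-specific tallies), not only the three stage contrasts.
#' @return Named list of per-contrast results, each a list with
#'   `comparison` (`c(later, earlier)` time points), `table` (feature_id,
#'   baseMean, log2FC, SE, p, padj, call), `up_set`, `down_set`, `alpha`.
#'   Class `stage_de`.
#' @export
stage_de <- function(cm, alpha = 0.05, all_pairs = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  tps <- trial_timepoints()
  have <- unique(cm$samples$timepoint)
  if (!all(tps %in% have)) {
    stop("missing time point(s) ", paste(setdiff(tps, have), collapse = ", "),
         "; available: ", paste(have, collapse = ", "))
  }
  tab_reps <- table(cm$samples$timepoint)
  if (any(tab_reps < 2)) {
    stop("every time point needs >= 2 replicates for testing")
  }
  if (min(tab_reps) == 2) {
    warning("only 2 replicates at some time points: statistical power is minimal",
            call. = FALSE)
  }

  sf <- size_factors(cm$counts, pseudo_reference = TRUE)
  disp <- estimate_dispersion(cm$counts, cm$samples$timepoint, sf = sf)

  contrasts <- stage_definitions()
  if (all_pairs) {
    extra <- utils::combn(tps, 2, simplify = FALSE)
    for (pr in extra) {
      lab <- paste0(pr[2], "_vs_", pr[1])
      if (!any(vapply(contrasts, function(x) identical(x, c(pr[2], pr[1])),
                      logical(1)))) {
        contrasts[[lab]] <- c(pr[2], pr[1])
      }
    }
  }

  out <- lapply(contrasts, function(cmp) {
    later <- cmp[1]; earlier <- cmp[2]
    idx_a <- which(cm$samples$timepoint == earlier)
    idx_b <- which(cm$samples$timepoint == later)
    res <- nb_wald(cm$counts[, idx_a, drop = FALSE],
                   cm$counts[, idx_b, drop = FALSE],
                   sf[idx_a], sf[idx_b], disp)
    res$padj <- NA_real_
    tested <- !res$all_zero
    res$padj[tested] <- bh_adjust(res$p[tested])
    res$call <- "ns"
    res$call[tested & res$padj < alpha & res$log2FC > 0] <- "up"
    res$call[tested & res$padj < alpha & res$log2FC < 0] <- "down"
    list(
      comparison = cmp,
      table = res[c("feature_id", "baseMean", "log2FC", "SE", "p", "padj",
                    "call")],
      up_set = res$feature_id[res$call == "up"],
      down_set = res$feature_id[res$call == "down"],
      n_excluded_all_zero = sum(res$all_zero),
      alpha = alpha
    )
  })
  structure(out, class = "stage_de", size_factors = sf)
}

#' Write stage-wise DE tables to TSV
#'
#' One file per contrast, named `<prefix><stage>.tsv`, with columns
#' feature_id, log2FC, SE, p, padj, call.
#'
#' @param de A `stage_de` result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, e.g. `"gut_mrna_"`.
#' @return Invisibly, the written paths.
#' @export
write_stage_de <- function(de, dir, prefix = "") {
  stopifnot(inherits(de, "stage_de"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(de), function(stage) {
    path <- file.path(dir, paste0(prefix, stage, ".tsv"))
    utils::write.table(de[[stage]]$table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}
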