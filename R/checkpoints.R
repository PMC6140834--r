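#' Comparison label for a time-point pair
#' @param later,earlier Time-point labels.
#' @return `"<later>_vs_<earlier>"`.
#' @export
comparison_label <- function(later, earlier) paste0(later, "_vs_", earlier)

#' Comparisons required by the checkpoint rule for a tissue
#'
#' The gut rule inspects 7w vs 5w, 7w vs 3w and 7w vs 0d; the liver rule
#' inspects 3w vs 0d, 5w vs 0d and 7w vs 0d.
#'
#' @param tissue `"gut"` or `"liver"`.
#' @return Named list of `c(later, earlier)` pairs.
#' @export
checkpoint_comparisons <- function(tissue) {
  tissue <- match.arg(tissue, c("gut", "liver"))
  pairs <- if (tissue == "gut") {
    list(c("7w", "5w"), c("7w", "3w"), c("7w", "0d"))
  } else {
    list(c("3w", "0d"), c("5w", "0d"), c("7w", "0d"))
  }
  stats::setNames(pairs, vapply(pairs, function(p) comparison_label(p[1], p[2]),
                                character(1)))
}

#' Category-level expression profile
#'
#' Aggregates normalized expression to the immune (process, category) level:
#' for each category and sample, the mean of `log2(normalized count + 1)`
#' over the category's member genes present in the matrix. Categories with
#' no member gene in the matrix are dropped (with a message).
#'
#' @param cm A `count_matrix`.
#' @param lib An `immune_library`.
#' @param sf Size factors (defaults to [size_factors()] with
#'   pseudo-reference fallback).
#' @return Object of class `category_profile`: list with `profile` (matrix,
#'   categories x samples), `info` (data frame process, category, n_genes,
#'   member_gene_ids), `samples` (the sample sheet).
#' @export
category_profile <- function(cm, lib, sf = NULL) {
  stopifnot(inherits(cm, "count_matrix"), inherits(lib, "immune_library"))
  if (is.null(sf)) sf <- size_factors(cm$counts, pseudo_reference = TRUE)
  logn <- log2(sweep(cm$counts, 2, sf, "/") + 1)

  rec <- lib$records
  rec$key <- paste(rec$process, rec$category, sep = " / ")
  keys <- unique(rec$key)
  rows <- list(); info <- list()
  for (kk in keys) {
    genes <- unique(rec$gene_id[rec$key == kk])
    present <- intersect(genes, rownames(logn))
    if (length(present) == 0) next
    rows[[kk]] <- colMeans(logn[present, , drop = FALSE])
    first <- rec[rec$key == kk, ][1, ]
    info[[kk]] <- data.frame(
      process = first$process, category = first$category,
      n_genes = length(present),
      member_gene_ids = paste(sort(present), collapse = ";")
    )
  }
  n_dropped <- length(keys) - length(rows)
  if (n_dropped > 0) {
    message(n_dropped, " categor(ies) with no expressed member genes dropped")
  }
  if (length(rows) == 0) stop("no library category has member genes in the matrix")
  profile <- do.call(rbind, rows)
  info <- do.call(rbind, info)
  rownames(info) <- NULL
  structure(list(profile = profile, info = info, samples = cm$samples),
            class = "category_profile")
}

# two-sample t-test with the degenerate-case convention used throughout:
# both groups constant and equal -> p = 1; constant and different -> p = 0.
two_sample_p <- function(a, b, var_equal = FALSE) {
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  stats::t.test(a, b, var.equal = var_equal)$p.value
}

welch_p <- function(a, b) two_sample_p(a, b, var_equal = FALSE)

#' Category-level t-tests across time points
#'
#' Two-sided t-tests on category mean log2 normalized expression between
#' replicate groups of the requested time-point pairs, with BH adjustment
#' across categories within each comparison. The default is the
#' pooled-variance Student t: at the trial's three replicates per time
#' point the Welch-Satterthwaite degrees of freedom collapse to about two,
#' which starves the BH-adjusted checkpoint rule of power, while the
#' category aggregates have near-equal group variances by construction.
#' Set `var_equal = FALSE` for the Welch variant.
#'
#' @param profile A `category_profile`.
#' @param comparisons Named list of `c(later, earlier)` time-point pairs
#'   (e.g. [checkpoint_comparisons()]).
#' @param alpha Significance threshold on the adjusted p (default 0.05),
#'   recorded for downstream use.
#' @param var_equal Pool the group variances (default `TRUE`).
#' @return Object of class `category_tests`: list with `tests` (data frame
#'   process, category, comparison, p, padj), `info`, `alpha`.
#' @export
category_tests <- function(profile, comparisons, alpha = 0.05,
                           var_equal = TRUE) {
  stopifnot(inherits(profile, "category_profile"))
  tp <- profile$samples$timepoint
  out <- list()
  for (lab in names(comparisons)) {
    pair <- comparisons[[lab]]
    idx_b <- which(tp == pair[1]); idx_a <- which(tp == pair[2])
    if (length(idx_a) < 2 || length(idx_b) < 2) {
      stop("comparison ", lab, " needs >= 2 replicates per time point")
    }
    p <- apply(profile$profile, 1, function(v) {
      two_sample_p(v[idx_a], v[idx_b], var_equal = var_equal)
    })
    out[[lab]] <- data.frame(
      process = profile$info$process, category = profile$info$category,
      comparison = lab, p = p, padj = bh_adjust(p), row.names = NULL
    )
  }
  tests <- do.call(rbind, out)
  rownames(tests) <- NULL
  structure(list(tests = tests, info = profile$info, alpha = alpha),
            class = "category_tests")
}

#' Select immune checkpoint categories
#'
#' Applies the tissue-specific homeostasis rule to the category-level test
#' results. Gut: a category is selected when it differs significantly
#' between 7w and 5w (or 7w and 3w) but not between 7w and 0d — i.e. it was
#' perturbed during the trial and returned to baseline. Liver: a category
#' is selected when it differs significantly between 0d and 3w (or 5w, or
#' 7w) — i.e. it departed from baseline at any point (the liver rule, as
#' printed, carries no return-to-baseline clause and is applied literally).
#'
#' Significance inside the rule uses the BH-adjusted p below `alpha` by
#' default (`use_adjusted = FALSE` switches to raw p).
#'
#' @param tests A `category_tests` containing the comparisons the tissue
#'   rule needs (see [checkpoint_comparisons()]).
#' @param tissue `"gut"` or `"liver"`.
#' @param alpha Significance threshold (defaults to the one stored in
#'   `tests`).
#' @param use_adjusted Use BH-adjusted p inside the rule (default `TRUE`).
#' @return Data frame (class `checkpoint_table`) with one row per category:
#'   `tissue`, `process`, `category`, `member_gene_ids`, one `p_*`/`padj_*`
#'   pair per comparison, `selected`, `rule_trace`.
#' @export
select_checkpoints <- function(tests, tissue, alpha = NULL,
                               use_adjusted = TRUE) {
  stopifnot(inherits(tests, "category_tests"))
  tissue <- match.arg(tissue, c("gut", "liver"))
  if (is.null(alpha)) alpha <- tests$alpha
  need <- names(checkpoint_comparisons(tissue))
  have <- unique(tests$tests$comparison)
  miss <- setdiff(need, have)
  if (length(miss)) {
    stop("missing required comparison(s) for the ", tissue, " rule: ",
         paste(miss, collapse = ", "))
  }

  info <- tests$info
  key <- paste(info$process, info$category, sep = " / ")
  wide <- data.frame(tissue = tissue, process = info$process,
                     category = info$category,
                     member_gene_ids = info$member_gene_ids,
                     stringsAsFactors = FALSE)
  sig <- matrix(NA, nrow(info), length(need),
                dimnames = list(key, need))
  for (cmp in need) {
    sub <- tests$tests[tests$tests$comparison == cmp, ]
    ord <- match(key, paste(sub$process, sub$category, sep = " / "))
    wide[[paste0("p_", cmp)]] <- sub$p[ord]
    wide[[paste0("padj_", cmp)]] <- sub$padj[ord]
    pv <- if (use_adjusted) sub$padj[ord] else sub$p[ord]
    sig[, cmp] <- pv < alpha
  }

  if (tissue == "gut") {
    hit <- (sig[, "7w_vs_5w"] | sig[, "7w_vs_3w"]) & !sig[, "7w_vs_0d"]
    trace <- sprintf("sig(7w_vs_5w)=%s|sig(7w_vs_3w)=%s&!sig(7w_vs_0d)=%s",
                     sig[, "7w_vs_5w"], sig[, "7w_vs_3w"], !sig[, "7w_vs_0d"])
  } else {
    hit <- sig[, "3w_vs_0d"] | sig[, "5w_vs_0d"] | sig[, "7w_vs_0d"]
    trace <- sprintf("sig(3w_vs_0d)=%s|sig(5w_vs_0d)=%s|sig(7w_vs_0d)=%s",
                     sig[, "3w_vs_0d"], sig[, "5w_vs_0d"], sig[, "7w_vs_0d"])
  }
  wide$selected <- as.logical(hit)
  wide$rule_trace <- trace
  class(wide) <- c("checkpoint_table", "data.frame")
  wide
}
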