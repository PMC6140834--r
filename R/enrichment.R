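#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `set_id`, `description`,
#' then member genes.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (set members); set names carry a
#'   `description` attribute vector.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(ln, 1, 60))
    sets[[parts[1]]] <- unique(parts[-(1:2)])
    desc[parts[1]] <- parts[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional named descriptions (defaults to set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, description[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a gene-set collection over a universe
#'
#' Sets are restricted to the universe; sets left empty by the restriction
#' are dropped.
#'
#' @param sets Named list of character vectors.
#' @param universe Character vector of background genes.
#' @return Object of class `gene_set_collection` with `sets`, `universe`.
#' @export
gene_set_collection <- function(sets, universe) {
  universe <- unique(as.character(universe))
  restricted <- lapply(sets, function(g) intersect(unique(g), universe))
  keep <- lengths(restricted) > 0
  structure(
    list(sets = restricted[keep], universe = universe,
         n_dropped_empty = sum(!keep)),
    class = "gene_set_collection"
  )
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` of which `K` are in the set, the probability of seeing at
#' least the observed overlap `k`. Computed stably in log space.
#'
#' @param k Observed overlap (DE genes in the set).
#' @param K Set size within the universe.
#' @param n Number of DE genes in the universe.
#' @param N Universe size.
#' @return The p-value.
#' @export
hypergeom_p <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    stop("inconsistent hypergeometric arguments: k=", k, " K=", K,
         " n=", n, " N=", N)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Gene-set over-representation with rich factors
#'
#' Tests each set of a collection for over-representation of `de_genes` by
#' the upper-tail hypergeometric test, reporting the rich factor `k / K`
#' (fraction of the set's universe genes that are differentially expressed)
#' and BH q-values computed across all sets with at least one hit. Rows are
#' sorted by q, then rich factor descending. DE genes outside the universe
#' are dropped (with a message giving the count).
#'
#' @param de_genes Character vector of differentially expressed genes.
#' @param collection A `gene_set_collection`.
#' @param alpha_q Significance threshold on q (default 0.05).
#' @return Data frame with columns `set_id`, `k`, `K`, `n`, `N`,
#'   `rich_factor`, `p`, `q`, `significant`. Empty (0 rows) when no DE gene
#'   remains after restriction to the universe.
#' @export
enrich <- function(de_genes, collection, alpha_q = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  de_genes <- unique(as.character(de_genes))
  n_out <- sum(!(de_genes %in% collection$universe))
  if (n_out > 0) {
    message(n_out, " DE gene(s) outside the universe dropped")
  }
  de <- intersect(de_genes, collection$universe)
  N <- length(collection$universe)
  n <- length(de)
  empty <- data.frame(set_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0),
                      rich_factor = numeric(0), p = numeric(0),
                      q = numeric(0), significant = logical(0))
  if (n == 0) return(empty)
  rows <- lapply(names(collection$sets), function(id) {
    members <- collection$sets[[id]]
    K <- length(members)
    k <- length(intersect(de, members))
    if (k == 0) return(NULL)
    data.frame(set_id = id, k = k, K = K, n = n, N = N,
               rich_factor = k / K, p = hypergeom_p(k, K, n, N))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(empty)
  rows$q <- bh_adjust(rows$p)
  rows$significant <- rows$q < alpha_q
  rows <- rows[order(rows$q, -rows$rich_factor, rows$set_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
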