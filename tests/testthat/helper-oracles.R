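# Independent oracles used to check the package implementations.
# These stay deliberately naive: direct transcriptions of the definitions.

# step-up BH, written from the definition: sort p, padj_(i) = min_{j>=i} p_(j)*m/j
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- sorted * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(1, adj)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# exhaustive hypergeometric upper tail from the counting definition
enum_hypergeom_p <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# a toy immune library used across tests
toy_library <- function() {
  immune_library(data.frame(
    gene_id = c("g1", "g2", "g3"),
    process = c("complement system", "pattern recognition",
                "complement system"),
    category = c("C3", "C-type lectin", "C1q")
  ))
}

# small count_matrix over the four canonical time points
toy_count_matrix <- function(counts, reps = 3, tissue = "gut") {
  tps <- trial_timepoints()
  sheet <- data.frame(
    sample_id = paste0("s", seq_len(length(tps) * reps)),
    tissue = tissue,
    timepoint = rep(tps, each = reps),
    replicate = rep(seq_len(reps), times = length(tps))
  )
  colnames(counts) <- sheet$sample_id
  count_matrix(counts, sheet)
}

# counts whose log2(count + 1) per-time-point profile is exactly `prof`,
# padded with constant features so that size factors are 1
profile_count_matrix <- function(profiles, reps = 1, tissue = "gut") {
  counts <- do.call(rbind, lapply(profiles, function(pr) {
    rep(2^pr - 1, each = reps)
  }))
  rownames(counts) <- names(profiles)
  pad <- matrix(100, nrow = 5, ncol = ncol(counts),
                dimnames = list(paste0("pad", 1:5), NULL))
  toy_count_matrix(rbind(counts, pad), reps = reps, tissue = tissue)
}
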