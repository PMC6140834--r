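#' Read a miRNA-to-target map from TSV
#'
#' Two tab-separated columns `mirna_id`, `gene_id` (header required), one
#' predicted target relation per row; duplicate pairs are collapsed.
#'
#' @param path Path to the TSV file.
#' @param source_tag Provenance label stored on the map.
#' @return Object of class `target_map`: data frame `mirna_id`, `gene_id`.
#' @export
read_target_map <- function(path, source_tag = basename(path)) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "")
  target_map(tab, source_tag = source_tag)
}

#' Construct a target map
#' @param pairs Data frame with columns `mirna_id`, `gene_id`.
#' @param source_tag Provenance label.
#' @return A `target_map`.
#' @export
target_map <- function(pairs, source_tag = "unspecified") {
  needed <- c("mirna_id", "gene_id")
  if (!all(needed %in% names(pairs))) {
    stop("target map needs columns mirna_id, gene_id")
  }
  pairs <- pairs[needed]
  pairs[] <- lapply(pairs, function(x) trimws(as.character(x)))
  if (any(!nzchar(pairs$mirna_id)) || any(!nzchar(pairs$gene_id))) {
    stop("empty identifier in target map")
  }
  pairs <- pairs[!duplicated(paste(pairs$mirna_id, pairs$gene_id, sep = "\r")), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  structure(pairs, class = c("target_map", "data.frame"),
            source_tag = source_tag)
}

# per-time-point mean of log2(normalized + 1), features x time points
timepoint_profile <- function(cm, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(cm$counts, pseudo_reference = TRUE)
  logn <- log2(sweep(cm$counts, 2, sf, "/") + 1)
  tps <- intersect(trial_timepoints(), unique(cm$samples$timepoint))
  prof <- sapply(tps, function(tp) {
    rowMeans(logn[, cm$samples$timepoint == tp, drop = FALSE])
  })
  colnames(prof) <- tps
  prof
}

#' Pearson correlations of miRNA-target pairs over the time course
#'
#' For every pair in the target map whose members appear in both matrices,
#' computes the Pearson correlation between the miRNA's and the gene's
#' per-time-point mean `log2(normalized count + 1)` profiles over the
#' shared time points. The replicate numbers of the two assays differ
#' (mRNA n = 3, miRNA n = 2), so per-time-point means are the pairing
#' substrate. Pairs with zero variance on either side have no defined
#' correlation and are dropped (with a message).
#'
#' @param mir_cm miRNA `count_matrix`.
#' @param mrna_cm mRNA `count_matrix`.
#' @param targets A `target_map`.
#' @return Data frame `mirna_id`, `gene_id`, `r`, `n_points`.
#' @export
pair_correlations <- function(mir_cm, mrna_cm, targets) {
  stopifnot(inherits(mir_cm, "count_matrix"),
            inherits(mrna_cm, "count_matrix"),
            inherits(targets, "target_map"))
  mir_prof <- timepoint_profile(mir_cm)
  mrna_prof <- timepoint_profile(mrna_cm)
  shared <- intersect(colnames(mir_prof), colnames(mrna_prof))
  if (length(shared) < 3) {
    stop("need >= 3 shared time points; found ", length(shared))
  }
  mir_prof <- mir_prof[, shared, drop = FALSE]
  mrna_prof <- mrna_prof[, shared, drop = FALSE]

  keep <- targets$mirna_id %in% rownames(mir_prof) &
          targets$gene_id %in% rownames(mrna_prof)
  pairs <- targets[keep, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      r = numeric(0), n_points = integer(0)))
  }
  x <- mir_prof[pairs$mirna_id, , drop = FALSE]
  y <- mrna_prof[pairs$gene_id, , drop = FALSE]
  sdx <- apply(x, 1, stats::sd); sdy <- apply(y, 1, stats::sd)
  defined <- sdx > 0 & sdy > 0
  if (any(!defined)) {
    message(sum(!defined), " pair(s) with a flat profile dropped (r undefined)")
  }
  r <- rep(NA_real_, nrow(pairs))
  if (any(defined)) {
    xs <- x[defined, , drop = FALSE]; ys <- y[defined, , drop = FALSE]
    xc <- xs - rowMeans(xs); yc <- ys - rowMeans(ys)
    r[defined] <- rowSums(xc * yc) /
      sqrt(rowSums(xc^2) * rowSums(yc^2))
  }
  out <- data.frame(mirna_id = pairs$mirna_id, gene_id = pairs$gene_id,
                    r = r, n_points = length(shared), row.names = NULL)
  out[defined, , drop = FALSE]
}

#' Stage-wise signed interaction network
#'
#' Builds the miRNA-mRNA network for one stage: an edge exists for every
#' predicted target pair whose miRNA and gene are both differentially
#' expressed in that stage. Direction attributes (`up`/`down`) come from
#' the DE calls; the edge sign is the sign of the Pearson correlation.
#'
#' @param correlations Output of [pair_correlations()].
#' @param mirna_de,mrna_de Single-contrast elements of a [stage_de()]
#'   result (e.g. `de$early`) for the miRNA and mRNA assays of the same
#'   stage.
#' @param stage Stage label stored on the edges.
#' @return Data frame (class `mir_network`) with columns `mirna_id`,
#'   `gene_id`, `r`, `sign`, `mirna_dir`, `gene_dir`, `stage`; a
#'   `cell_counts` attribute tabulates edges per
#'   (mirna_dir, gene_dir, sign).
#' @export
stage_network <- function(correlations, mirna_de, mrna_de, stage) {
  mir_dir <- c(stats::setNames(rep("up", length(mirna_de$up_set)), mirna_de$up_set),
               stats::setNames(rep("down", length(mirna_de$down_set)), mirna_de$down_set))
  gene_dir <- c(stats::setNames(rep("up", length(mrna_de$up_set)), mrna_de$up_set),
                stats::setNames(rep("down", length(mrna_de$down_set)), mrna_de$down_set))
  keep <- correlations$mirna_id %in% names(mir_dir) &
          correlations$gene_id %in% names(gene_dir)
  edges <- correlations[keep, , drop = FALSE]
  edges$sign <- ifelse(edges$r >= 0, "positive", "negative")
  edges$mirna_dir <- unname(mir_dir[edges$mirna_id])
  edges$gene_dir <- unname(gene_dir[edges$gene_id])
  edges$stage <- rep(stage, nrow(edges))
  edges <- edges[c("mirna_id", "gene_id", "r", "sign", "mirna_dir",
                   "gene_dir", "stage")]
  rownames(edges) <- NULL
  cells <- table(mirna_dir = edges$mirna_dir, gene_dir = edges$gene_dir,
                 sign = edges$sign)
  structure(edges, class = c("mir_network", "data.frame"),
            cell_counts = cells)
}

#' Restrict a network to immune targets
#'
#' Keeps only edges whose target gene is in the immune gene library, and
#' summarizes them per immune process in the style of the stage-wise
#' miRNA-target tables: per (stage, gene direction, immune process), the
#' miRNA(gene) pairs, the distinct target gene count, and the categories
#' involved.
#'
#' @param edges A `mir_network`.
#' @param lib An `immune_library`.
#' @return List with `edges` (immune subset, `immune = TRUE` column added)
#'   and `summary` (data frame stage, gene_dir, process, n_genes,
#'   mirna_targets, categories).
#' @export
immune_subnetwork <- function(edges, lib) {
  stopifnot(inherits(lib, "immune_library"))
  rec <- lib$records
  sub <- edges[edges$gene_id %in% rec$gene_id, , drop = FALSE]
  sub$immune <- rep(TRUE, nrow(sub))
  rownames(sub) <- NULL
  if (nrow(sub) == 0) {
    return(list(edges = sub,
                summary = data.frame(stage = character(0),
                                     gene_dir = character(0),
                                     process = character(0),
                                     n_genes = integer(0),
                                     mirna_targets = character(0),
                                     categories = character(0))))
  }
  ann <- merge(sub, rec, by = "gene_id")
  grp <- split(ann, list(ann$stage, ann$gene_dir, ann$process), drop = TRUE)
  summary <- do.call(rbind, lapply(grp, function(g) {
    pair_lab <- vapply(split(g$gene_id, g$mirna_id), function(genes) {
      paste0(unique(genes), collapse = ", ")
    }, character(1))
    data.frame(
      stage = g$stage[1], gene_dir = g$gene_dir[1], process = g$process[1],
      n_genes = length(unique(g$gene_id)),
      mirna_targets = paste(sprintf("%s (%s)", names(pair_lab), pair_lab),
                            collapse = "; "),
      categories = paste(sort(unique(g$category)), collapse = "; ")
    )
  }))
  rownames(summary) <- NULL
  list(edges = sub, summary = summary)
}

#' Export a network to SIF, attribute TSVs and GraphML
#'
#' Writes `<prefix>.sif` (one `mirna regulates gene` line per edge),
#' `<prefix>_nodes.tsv` (node id, type, regulation), `<prefix>_edges.tsv`
#' (all edge attributes) and `<prefix>.graphml`. The node attribute
#' `regulation` is `up`/`down` for both node classes (the red/green
#' encoding of the interaction figures).
#'
#' @param edges A `mir_network` (may have zero rows).
#' @param prefix Output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
export_network <- function(edges, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  sif_path <- paste0(prefix, ".sif")
  nodes_path <- paste0(prefix, "_nodes.tsv")
  edges_path <- paste0(prefix, "_edges.tsv")
  graphml_path <- paste0(prefix, ".graphml")

  writeLines(sprintf("%s\tregulates\t%s", edges$mirna_id, edges$gene_id),
             sif_path)
  nodes <- rbind(
    data.frame(id = edges$mirna_id,
               type = rep("miRNA", nrow(edges)),
               regulation = edges$mirna_dir),
    data.frame(id = edges$gene_id,
               type = rep("mRNA", nrow(edges)),
               regulation = edges$gene_dir)
  )
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  utils::write.table(nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(edges), edges_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$mirna_id, to = edges$gene_id,
                   r = edges$r, sign = edges$sign,
                   stage = edges$stage),
    directed = TRUE, vertices = nodes
  )
  igraph::write_graph(g, graphml_path, format = "graphml")
  invisible(c(sif_path, nodes_path, edges_path, graphml_path))
}

#' Re-import a GraphML network export
#'
#' @param graphml_path Path written by [export_network()].
#' @return Data frame of edges with `mirna_id`, `gene_id`, `r`, `sign`,
#'   `stage`, plus the node table as attribute `nodes`.
#' @export
import_network <- function(graphml_path) {
  g <- igraph::read_graph(graphml_path, format = "graphml")
  ed <- igraph::as_data_frame(g, what = "edges")
  vd <- igraph::as_data_frame(g, what = "vertices")
  if (nrow(ed)) {
    names(ed)[1:2] <- c("mirna_id", "gene_id")
  } else {
    ed <- data.frame(mirna_id = character(0), gene_id = character(0),
                     r = numeric(0), sign = character(0),
                     stage = character(0))
  }
  attr(ed, "nodes") <- vd
  ed
}
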