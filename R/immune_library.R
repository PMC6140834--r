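#' Canonical immune process labels
#'
#' The two-level immune gene library classifies genes into nine top-level
#' immune processes (first level) and free-text immune gene categories
#' (second level, e.g. "C1q", "C-type lectin", "plasminogen"). The nine
#' process labels are fixed; any other label is rejected at load time.
#'
#' @return Character vector of the nine canonical process labels, in
#'   conventional display order.
#' @export
immune_process_labels <- function() {
  c(
    "acute phase reactions",
    "pattern recognition",
    "antigen processing and regulators",
    "complement system",
    "inflammatory cytokines and receptors",
    "adapters, effectors and signal transducers",
    "innate immune cells related",
    "T/B cell antigen activation",
    "other genes related to immune response"
  )
}

# case-insensitive, whitespace-normalized form used for matching categories
# and process labels (the source tables mix capitalizations)
normalize_label <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Construct an immune gene library
#'
#' @param records Data frame with columns `gene_id`, `process`, `category`.
#'   Duplicate identical rows (after label normalization) are collapsed; a
#'   gene may appear under several (process, category) pairs.
#' @return An object of class `immune_library`: a list with `records`
#'   (collapsed data frame) and `process_labels`.
#' @export
immune_library <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("gene_id", "process", "category")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("immune library table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  records <- records[needed]
  records[] <- lapply(records, as.character)

  bad_gene <- which(is.na(records$gene_id) | !nzchar(trimws(records$gene_id)))
  if (length(bad_gene)) {
    stop("empty gene_id at row(s): ", paste(bad_gene, collapse = ", "))
  }

  canon <- immune_process_labels()
  idx <- match(normalize_label(records$process), normalize_label(canon))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop("unknown immune process label ",
         paste0("'", records$process[bad[1]], "'"),
         " at row(s): ", paste(bad, collapse = ", "),
         "; allowed labels are the nine canonical immune processes ",
         "(see immune_process_labels())")
  }
  records$process <- canon[idx]
  records$gene_id <- trimws(records$gene_id)
  records$category <- gsub("\\s+", " ", trimws(records$category))

  key <- paste(records$gene_id, records$process,
               normalize_label(records$category), sep = "\r")
  records <- records[!duplicated(key), , drop = FALSE]
  rownames(records) <- NULL

  structure(
    list(records = records, process_labels = canon),
    class = "immune_library"
  )
}

#' Load an immune gene library from a TSV file
#'
#' Expects a UTF-8 tab-separated file with header columns
#' `gene_id`, `process`, `category`. Rows carrying a process label outside
#' the nine canonical immune processes, or an empty gene id, raise an error
#' naming the offending row.
#'
#' @param path Path to the TSV file.
#' @return An `immune_library` object.
#' @export
load_immune_library <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
  lib <- immune_library(tab)
  tallies <- table(lib$records$process)
  message(sprintf("immune library: %d records, %d distinct genes, %d processes in use",
                  nrow(lib$records), length(unique(lib$records$gene_id)),
                  length(tallies)))
  lib
}

#' Write an immune gene library to TSV
#'
#' @param lib An `immune_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_immune_library <- function(lib, path) {
  stopifnot(inherits(lib, "immune_library"))
  utils::write.table(lib$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.immune_library <- function(x, ...) {
  cat("Immune gene library:", nrow(x$records), "records,",
      length(unique(x$records$gene_id)), "distinct genes\n")
  print(table(factor(x$records$process, levels = x$process_labels)))
  invisible(x)
}

#' Classify genes against the immune gene library
#'
#' Partitions an input gene list into (process, category) buckets according
#' to library membership. A gene annotated under several (process, category)
#' pairs is placed in every matching bucket (membership tallies therefore
#' count multiplicity); genes absent from the library go to `non_immune`.
#' Absence is not an error.
#'
#' @param gene_ids Character vector of gene identifiers (may be empty).
#' @param lib An `immune_library`.
#' @return A list with elements
#'   \describe{
#'     \item{partition}{data frame (process, category, gene_id), one row per
#'       membership of an input gene;}
#'     \item{buckets}{named list of gene vectors, keyed `process / category`;}
#'     \item{non_immune}{character vector of input genes not in the library;}
#'     \item{n_distinct_immune}{number of distinct input genes classified.}
#'   }
#' @export
classify_genes <- function(gene_ids, lib) {
  stopifnot(inherits(lib, "immune_library"))
  gene_ids <- unique(as.character(gene_ids))
  rec <- lib$records
  hit <- rec[rec$gene_id %in% gene_ids, , drop = FALSE]
  hit <- hit[c("process", "category", "gene_id")]
  hit <- hit[order(match(hit$process, lib$process_labels),
                   normalize_label(hit$category), hit$gene_id), , drop = FALSE]
  rownames(hit) <- NULL
  non_immune <- setdiff(gene_ids, rec$gene_id)
  buckets <- if (nrow(hit)) {
    split(hit$gene_id, paste(hit$process, hit$category, sep = " / "))
  } else {
    list()
  }
  list(
    partition = hit,
    buckets = buckets,
    non_immune = non_immune,
    n_distinct_immune = length(unique(hit$gene_id))
  )
}
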