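#' Run configuration for the full analysis
#'
#' Bundles the significance thresholds of the study (DE adjusted p 0.05,
#' enrichment q 0.05, category/checkpoint adjusted p 0.05, growth 0.05,
#' morphometry 0.01), the stage definitions, the seed and the output
#' directory.
#'
#' @param seed Integer seed driving the simulation.
#' @param out_dir Output directory of the run.
#' @param alpha_de DE calling threshold on adjusted p (default 0.05).
#' @param alpha_q Enrichment significance threshold on q (default 0.05).
#' @param alpha_checkpoint Category-test threshold (default 0.05).
#' @param alpha_growth Growth-comparison threshold (default 0.05).
#' @param alpha_morph Morphometry-comparison threshold (default 0.01).
#' @param immune_filter `"before"` restricts DE gene lists to immune
#'   library genes before enrichment testing (the default, matching an
#'   immune-gene enrichment question); `"after"` tests all DE genes.
#' @param sim A [sim_config()] (defaults to `sim_config(seed)`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed, out_dir,
                       alpha_de = 0.05, alpha_q = 0.05,
                       alpha_checkpoint = 0.05,
                       alpha_growth = 0.05, alpha_morph = 0.01,
                       immune_filter = c("before", "after"),
                       sim = sim_config(seed)) {
  immune_filter <- match.arg(immune_filter)
  for (a in c(alpha_de, alpha_q, alpha_checkpoint, alpha_growth, alpha_morph)) {
    if (!(a > 0 && a < 1)) stop("alpha values must lie in (0, 1)")
  }
  structure(as.list(environment()), class = "run_config")
}

# per (stage, process) signed gene tallies: up counts positive, down
# counts negative (the barplot convention of the stage-wise summaries)
process_tallies <- function(de, lib, tissue) {
  rows <- list()
  for (stage in names(stage_definitions())) {
    for (dir in c("up", "down")) {
      genes <- if (dir == "up") de[[stage]]$up_set else de[[stage]]$down_set
      cls <- classify_genes(genes, lib)
      tab <- table(cls$partition$process)
      for (proc in names(tab)) {
        rows[[length(rows) + 1]] <- data.frame(
          tissue = tissue, stage = stage, process = proc, direction = dir,
          n_genes = if (dir == "down") -as.integer(tab[[proc]])
                    else as.integer(tab[[proc]])
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(tissue = character(0), stage = character(0),
                      process = character(0), direction = character(0),
                      n_genes = integer(0)))
  }
  do.call(rbind, rows)
}

write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Simulates the study inputs, then executes every analysis stage:
#' stage-wise differential expression of gut mRNA, liver mRNA and gut
#' miRNA; immune-library classification with signed per-process tallies;
#' immune gene-set enrichment per stage and direction; checkpoint selection
#' per tissue; stage-wise miRNA-mRNA networks with immune filtering and
#' Cytoscape-compatible export; growth and morphometry statistics. All
#' artifacts are written beneath `cfg$out_dir` along with a manifest
#' recording seeds and every threshold applied. Deterministic under the
#' config seed.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list with every in-memory intermediate (`sim`,
#'   `de`, `tallies`, `enrichment`, `checkpoints`, `networks`,
#'   `phenotype`, `manifest`) plus `out_dir`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- step("simulate", simulate_study(cfg$sim))
  step("simulate", write_sim_inputs(sim, file.path(out, "inputs")))

  de <- step("de", list(
    gut = stage_de(sim$gut_mrna, alpha = cfg$alpha_de),
    liver = stage_de(sim$liver_mrna, alpha = cfg$alpha_de),
    gut_mirna = suppressWarnings(stage_de(sim$gut_mirna,
                                          alpha = cfg$alpha_de))
  ))
  for (nm in names(de)) {
    write_stage_de(de[[nm]], file.path(out, "de"), paste0(nm, "_"))
  }

  tallies <- step("classify", rbind(
    process_tallies(de$gut, sim$library, "gut"),
    process_tallies(de$liver, sim$library, "liver")
  ))
  write_tsv(tallies, file.path(out, "classify", "process_tallies.tsv"))

  enr <- step("enrich", {
    rows <- list()
    for (tissue in c("gut", "liver")) {
      universe <- rownames(if (tissue == "gut") sim$gut_mrna$counts
                           else sim$liver_mrna$counts)
      coll <- gene_set_collection(sim$gene_sets, universe)
      for (stage in names(stage_definitions())) {
        for (dir in c("up", "down")) {
          genes <- if (dir == "up") de[[tissue]][[stage]]$up_set
                   else de[[tissue]][[stage]]$down_set
          if (cfg$immune_filter == "before") {
            genes <- intersect(genes, sim$library$records$gene_id)
          }
          tab <- enrich(genes, coll, alpha_q = cfg$alpha_q)
          if (nrow(tab)) {
            tab <- cbind(tissue = tissue, stage = stage, direction = dir,
                         tab)
            rows[[length(rows) + 1]] <- tab
          }
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(tissue = character(0), stage = character(0),
                 direction = character(0), set_id = character(0))
  })
  write_tsv(enr, file.path(out, "enrich", "enrichment.tsv"))

  checkpoints <- step("checkpoints", {
    res <- list()
    for (tissue in c("gut", "liver")) {
      cm <- if (tissue == "gut") sim$gut_mrna else sim$liver_mrna
      prof <- suppressMessages(category_profile(cm, sim$library))
      tests <- category_tests(prof, checkpoint_comparisons(tissue),
                              alpha = cfg$alpha_checkpoint)
      res[[tissue]] <- select_checkpoints(tests, tissue)
      write_tsv(res[[tissue]],
                file.path(out, "checkpoints",
                          paste0(tissue, "_checkpoints.tsv")))
    }
    res
  })

  networks <- step("network", {
    corr <- suppressMessages(
      pair_correlations(sim$gut_mirna, sim$gut_mrna, sim$targets))
    nets <- list()
    for (stage in names(stage_definitions())) {
      net <- stage_network(corr, de$gut_mirna[[stage]], de$gut[[stage]],
                           stage)
      imm <- immune_subnetwork(net, sim$library)
      export_network(net, file.path(out, "network", paste0(stage, "_all")))
      export_network(imm$edges,
                     file.path(out, "network", paste0(stage, "_immune")))
      nets[[stage]] <- list(all = net, immune = imm)
    }
    summary <- do.call(rbind, lapply(nets, function(x) x$immune$summary))
    if (is.null(summary)) summary <- data.frame()
    write_tsv(summary, file.path(out, "network", "immune_pairs_summary.tsv"))
    nets
  })

  phenotype <- step("phenotype", {
    growth <- sim$phenotype$growth
    metrics <- t(apply(growth, 1, function(r) {
      growth_metrics(as.list(r)[setdiff(names(growth), c("group", "cage"))])
    }))
    met <- data.frame(group = growth$group, cage = growth$cage, metrics)
    write_tsv(met, file.path(out, "phenotype", "growth_metrics.tsv"))
    comps <- list()
    for (g in setdiff(unique(met$group), "FM")) {
      for (m in setdiff(colnames(metrics), NULL)) {
        a <- met[met$group == "FM", m]; b <- met[met$group == g, m]
        if (stats::var(a) == 0 && stats::var(b) == 0 &&
            isTRUE(all.equal(mean(a), mean(b)))) next
        cmpr <- group_compare(a, b, alpha = cfg$alpha_growth)
        comps[[length(comps) + 1]] <- data.frame(
          metric = m, group = g, mean_fm = mean(a), mean_group = mean(b),
          p = cmpr$p, significant = cmpr$significant)
      }
    }
    comps <- if (length(comps)) do.call(rbind, comps) else data.frame()
    write_tsv(comps, file.path(out, "phenotype", "group_comparisons.tsv"))
    dens <- mean_density(sim$phenotype$density$intensity,
                         sim$phenotype$density$signal_mask,
                         sim$phenotype$density$background_rois)
    areas <- vapply(sim$phenotype$masks, percent_area, numeric(1))
    write_tsv(data.frame(quantity = c("mean_density",
                                      paste0("percent_area_mask", seq_along(areas))),
                         value = c(dens, areas)),
              file.path(out, "phenotype", "morphometry.tsv"))
    list(metrics = met, comparisons = comps, mean_density = dens,
         percent_areas = areas)
  })

  manifest <- list(
    seed = cfg$seed,
    thresholds = list(de_padj = cfg$alpha_de, enrichment_q = cfg$alpha_q,
                      checkpoint_padj = cfg$alpha_checkpoint,
                      growth_p = cfg$alpha_growth,
                      morphometry_p = cfg$alpha_morph),
    immune_filter = cfg$immune_filter,
    stages = stage_definitions(),
    n_features = list(genes = nrow(sim$gut_mrna$counts),
                      mirnas = nrow(sim$gut_mirna$counts)),
    de_counts = lapply(de, function(d) lapply(d, function(s) {
      list(up = length(s$up_set), down = length(s$down_set))
    })),
    stages_completed = c("simulate", "de", "classify", "enrich",
                         "checkpoints", "network", "phenotype")
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  result <- list(sim = sim, de = de, tallies = tallies, enrichment = enr,
                 checkpoints = checkpoints, networks = networks,
                 phenotype = phenotype, manifest = manifest, out_dir = out)
  make_report(out)
  invisible(result)
}

#' Assemble the summary tables of a completed run
#'
#' Reads the artifacts of a [run_all()] directory and writes the three
#' summary tables to `<run_dir>/report/`: the stage-wise immune
#' classification tables for gut and liver (per stage and direction, the
#' DEG count, the per-process gene counts and the categories involved),
#' the checkpoint table, and the stage-wise immune miRNA-target pair table
#' with per-process gene counts.
#'
#' @param run_dir Directory of a completed run.
#' @return Invisibly, the written paths.
#' @export
make_report <- function(run_dir) {
  need <- c(file.path(run_dir, "inputs", "immune_library.tsv"),
            file.path(run_dir, "de", "gut_early.tsv"),
            file.path(run_dir, "checkpoints", "gut_checkpoints.tsv"),
            file.path(run_dir, "checkpoints", "liver_checkpoints.tsv"),
            file.path(run_dir, "network", "immune_pairs_summary.tsv"))
  miss <- need[!file.exists(need)]
  if (length(miss)) {
    stop("incomplete run; missing artifact(s):\n  ",
         paste(miss, collapse = "\n  "))
  }
  lib <- suppressMessages(
    load_immune_library(file.path(run_dir, "inputs", "immune_library.tsv")))
  rep_dir <- file.path(run_dir, "report")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)

  class_table <- function(tissue) {
    rows <- list()
    for (stage in names(stage_definitions())) {
      path <- file.path(run_dir, "de", paste0(tissue, "_", stage, ".tsv"))
      tab <- utils::read.delim(path)
      for (dir in c("up", "down")) {
        genes <- tab$feature_id[tab$call == dir]
        cls <- classify_genes(genes, lib)
        proc_tab <- table(cls$partition$process)
        rows[[length(rows) + 1]] <- data.frame(
          stage = stage, direction = toupper(dir),
          deg_total = length(genes),
          deg_immune = cls$n_distinct_immune,
          immune_process_gene_no = paste(
            sprintf("%s (%d)", names(proc_tab), as.integer(proc_tab)),
            collapse = "; "),
          immune_gene_categories = paste(
            unique(cls$partition$category), collapse = "; ")
        )
      }
    }
    do.call(rbind, rows)
  }
  paths <- character(0)
  paths <- c(paths, write_tsv(class_table("gut"),
                              file.path(rep_dir, "table3A_gut_immune_degs.tsv")))
  paths <- c(paths, write_tsv(class_table("liver"),
                              file.path(rep_dir, "table3B_liver_immune_degs.tsv")))

  chk <- do.call(rbind, lapply(c("gut", "liver"), function(tissue) {
    tab <- utils::read.delim(file.path(run_dir, "checkpoints",
                                       paste0(tissue, "_checkpoints.tsv")))
    tab[tab$selected %in% TRUE,
        c("tissue", "process", "category", "member_gene_ids")]
  }))
  paths <- c(paths, write_tsv(chk, file.path(rep_dir, "table4_checkpoints.tsv")))

  net <- utils::read.delim(file.path(run_dir, "network",
                                     "immune_pairs_summary.tsv"))
  if (nrow(net)) {
    net$process_gene_no <- sprintf("%s (%d)", net$process, net$n_genes)
  }
  paths <- c(paths, write_tsv(net, file.path(rep_dir,
                                             "table5_immune_mirna_pairs.tsv")))
  invisible(paths)
}
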