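#' @importFrom rlang .data
NULL

#' Pipeline configuration
#'
#' Bundles every knob of the supermatrix pipeline: input (a synthetic
#' configuration or a directory of per-locus FASTA + Newick files), the
#' support threshold for paralog pruning, the occupancy fraction, the IQR
#' multiplier and chi-square alpha for locus filtering, the gap fraction
#' for site trimming, and optional per-locus model selection.
#'
#' @param synthetic A [synthetic_config()], or `NULL` when reading from
#'   `input_dir`.
#' @param input_dir Directory with `<locus>.fasta` / `<locus>.nwk` pairs
#'   (used when `synthetic` is `NULL`).
#' @param n_total_taxa Total taxa for the occupancy rule; defaults to the
#'   synthetic configuration's taxon count or the number of distinct taxa
#'   observed in the input.
#' @param support_threshold Support collapse threshold (default 0.7).
#' @param occupancy_fraction Occupancy fraction in `(0, 1]`, or `NULL` to
#'   skip occupancy filtering (default 0.75).
#' @param iqr_multiplier IQR multiplier for locus elimination (default 1.5).
#' @param chisq_alpha Compositional chi-square alpha (default 0.05).
#' @param max_gap_fraction Gappy-site threshold (default 0.5); `NULL` skips
#'   trimming.
#' @param filter_loci Run the two-stage heterogeneity filter (default
#'   `TRUE`).
#' @param select_models Run per-locus model selection and record the chosen
#'   names in the partition table (default `FALSE`; records `"AUTO"`).
#' @param model_candidates Candidate model names for selection.
#' @param taxon_delim Delimiter separating taxon from copy in sequence ids.
#' @param out_dir Output directory, or `NULL` to keep everything in memory.
#' @param seed Integer seed (synthetic mode takes its own seed from
#'   `synthetic`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            input_dir = NULL, n_total_taxa = NULL,
                            support_threshold = 0.7,
                            occupancy_fraction = 0.75,
                            iqr_multiplier = 1.5, chisq_alpha = 0.05,
                            max_gap_fraction = 0.5, filter_loci = TRUE,
                            select_models = FALSE,
                            model_candidates = c("Poisson", "JTT", "WAG",
                                                 "LG"),
                            taxon_delim = "|", out_dir = NULL, seed = 1L) {
  stopifnot(!is.null(synthetic) || !is.null(input_dir),
            support_threshold >= 0, support_threshold <= 1,
            is.null(occupancy_fraction) ||
              (occupancy_fraction > 0 && occupancy_fraction <= 1),
            iqr_multiplier > 0, chisq_alpha >= 0, chisq_alpha <= 1,
            is.null(max_gap_fraction) ||
              (max_gap_fraction >= 0 && max_gap_fraction <= 1))
  structure(list(synthetic = synthetic, input_dir = input_dir,
                 n_total_taxa = n_total_taxa,
                 support_threshold = support_threshold,
                 occupancy_fraction = occupancy_fraction,
                 iqr_multiplier = iqr_multiplier,
                 chisq_alpha = chisq_alpha,
                 max_gap_fraction = max_gap_fraction,
                 filter_loci = filter_loci,
                 select_models = select_models,
                 model_candidates = model_candidates,
                 taxon_delim = taxon_delim, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `synthetic:` block mirrors [synthetic_config()].
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- if (!is.null(y$synthetic))
    do.call(synthetic_config, y$synthetic)
  y$synthetic <- NULL
  do.call(pipeline_config, c(list(synthetic = syn), y))
}

read_input_dir <- function(dir, delim) {
  fastas <- sort(list.files(dir, pattern = "\\.fasta$|\\.fa$",
                            full.names = TRUE))
  fastas <- fastas[basename(fastas) != "supermatrix.fasta"]
  ogs <- lapply(fastas, read_orthogroup, delim = delim)
  trees <- lapply(fastas, function(f) {
    nwk <- sub("\\.(fasta|fa)$", ".nwk", f)
    if (!file.exists(nwk)) stop("missing gene tree: ", nwk)
    read_gene_tree(nwk)
  })
  list(orthogroups = ogs, gene_trees = trees)
}

#' Run the supermatrix pipeline end to end
#'
#' Stages, in order: load or simulate orthogroups and gene trees; delete
#' duplicated records; tree-based paralog pruning; occupancy filtering;
#' branch-length and compositional heterogeneity filtering; gappy-site
#' removal; optional per-locus model selection; concatenation and summary.
#' Disabled stages are no-op pass-throughs.  Every per-locus decision is
#' logged; when `out_dir` is set, intermediates, the supermatrix (FASTA,
#' relaxed PHYLIP, RAxML partition file), the diagnostics and log tables
#' and a JSON manifest are written, and reruns with the same configuration
#' are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `supermatrix`, `summary`,
#'   `diagnostics`, `log` (tibble: stage, locus, action, cause), `manifest`
#'   (stage in/out counts and settings), plus the synthetic `truth` when
#'   applicable.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_rows <- list()
  log_add <- function(stage, locus, action, cause = "") {
    log_rows[[length(log_rows) + 1L]] <<-
      tibble::tibble(stage = stage, locus_id = locus, action = action,
                     cause = cause)
  }
  stages <- list()
  stage_count <- function(stage, n_in, n_out) {
    stages[[length(stages) + 1L]] <<-
      tibble::tibble(stage = stage, n_in = n_in, n_out = n_out)
  }

  # ---- load ----
  truth <- NULL
  if (!is.null(config$synthetic)) {
    ds <- generate_dataset(config$synthetic)
    ogs <- ds$orthogroups
    trees <- ds$gene_trees
    truth <- ds$truth
    n_total <- config$n_total_taxa %||% config$synthetic$n_taxa
  } else {
    inp <- read_input_dir(config$input_dir, config$taxon_delim)
    ogs <- inp$orthogroups
    trees <- inp$gene_trees
    n_total <- config$n_total_taxa %||%
      length(unique(unlist(lapply(ogs, og_taxa))))
  }
  stage_count("load", length(ogs), length(ogs))

  # ---- dedupe ----
  n_in <- length(ogs)
  ogs <- lapply(ogs, function(og) {
    out <- dedupe_records(og)
    if (og_n_records(out) < og_n_records(og))
      log_add("dedupe", og$locus_id, "deduplicated",
              sprintf("%d records removed",
                      og_n_records(og) - og_n_records(out)))
    out
  })
  stage_count("dedupe", n_in, length(ogs))

  # ---- paralog pruning ----
  pruned <- list(); pruned_trees <- list(); prune_reports <- list()
  for (i in seq_along(ogs)) {
    og <- ogs[[i]]
    tr <- trees[[i]]
    tr <- ape::keep.tip(tr, intersect(tr$tip.label, og$seq_id))
    out <- prune_orthogroup(og, tr, threshold = config$support_threshold,
                            delim = config$taxon_delim)
    rep_i <- attr(out, "report")
    prune_reports[[i]] <- rep_i
    if (rep_i$unusable || og_n_records(out) < 2) {
      log_add("prune", og$locus_id, "removed", "unusable after pruning")
      next
    }
    log_add("prune", og$locus_id, "kept",
            sprintf("%d/%d leaves retained", rep_i$leaves_out,
                    rep_i$leaves_in))
    pruned[[length(pruned) + 1L]] <- out
    pruned_trees[[length(pruned_trees) + 1L]] <-
      ape::keep.tip(tr, out$seq_id)
  }
  stage_count("prune", length(ogs), length(pruned))

  # ---- occupancy ----
  min_taxa <- NA_integer_
  if (!is.null(config$occupancy_fraction)) {
    occ <- occupancy_filter(pruned, config$occupancy_fraction, n_total)
    min_taxa <- occ$min_taxa
    keep <- occ$report$retained
    for (i in which(!keep))
      log_add("occupancy", occ$report$locus_id[i], "removed",
              sprintf("%d < %d taxa", occ$report$n_taxa[i], occ$min_taxa))
    pruned_trees <- pruned_trees[keep]
    n_in <- length(pruned)
    pruned <- occ$orthogroups
    stage_count("occupancy", n_in, length(pruned))
  }

  # ---- heterogeneity diagnostics and filtering ----
  diagnostics <- NULL
  if (config$filter_loci && length(pruned) > 0) {
    eligible <- vapply(pruned, function(o) length(og_taxa(o)) >= 3,
                       logical(1))
    diagnostics <- locus_diagnostics(pruned[eligible],
                                     pruned_trees[eligible])
    fl <- filter_loci(diagnostics, alpha = config$chisq_alpha,
                      multiplier = config$iqr_multiplier)
    diagnostics <- fl$report
    drop_ids <- setdiff(diagnostics$locus_id, fl$retained)
    for (j in seq_len(nrow(diagnostics))) {
      if (!diagnostics$retained[j])
        log_add("filter", diagnostics$locus_id[j], "removed",
                diagnostics$eliminated_by[j])
    }
    keep <- vapply(pruned, function(o)
      !(o$locus_id %in% drop_ids), logical(1))
    n_in <- length(pruned)
    pruned <- pruned[keep]
    pruned_trees <- pruned_trees[keep]
    stage_count("filter", n_in, length(pruned))
  }

  # ---- gappy-site removal ----
  if (!is.null(config$max_gap_fraction)) {
    pruned <- lapply(pruned, remove_gappy_sites,
                     max_gap_fraction = config$max_gap_fraction)
    empty <- vapply(pruned, function(o) og_length(o) == 0, logical(1))
    for (i in which(empty))
      log_add("trim", pruned[[i]]$locus_id, "removed", "no sites left")
    n_in <- length(pruned)
    pruned <- pruned[!empty]
    pruned_trees <- pruned_trees[!empty]
    stage_count("trim", n_in, length(pruned))
  }

  if (length(pruned) == 0)
    stop("pipeline stage 'concatenate' failed: no loci left")

  # ---- model selection ----
  models <- "AUTO"
  if (config$select_models) {
    models <- vapply(pruned, function(og) {
      select_model(og, config$model_candidates)$model
    }, character(1))
  }

  # ---- concatenate and summarise ----
  sm <- concatenate_orthogroups(pruned, models = models)
  summary <- summarize_supermatrix(sm)
  pm <- percent_missing(sm)

  log_tbl <- dplyr::bind_rows(log_rows)
  manifest <- list(
    package = "supermatrix",
    version = as.character(utils::packageVersion("supermatrix")),
    seed = if (!is.null(config$synthetic)) config$synthetic$seed
           else config$seed,
    n_total_taxa = n_total,
    min_taxa = min_taxa,
    settings = list(
      support_threshold = config$support_threshold,
      occupancy_fraction = config$occupancy_fraction,
      iqr_multiplier = config$iqr_multiplier,
      chisq_alpha = config$chisq_alpha,
      max_gap_fraction = config$max_gap_fraction,
      filter_loci = config$filter_loci,
      select_models = config$select_models),
    stages = dplyr::bind_rows(stages),
    summary = summary)

  res <- structure(
    list(supermatrix = sm, summary = summary,
         per_taxon_missing = pm$per_taxon, diagnostics = diagnostics,
         prune_report = dplyr::bind_rows(prune_reports), log = log_tbl,
         manifest = manifest, truth = truth),
    class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_result(res, config$out_dir)
  res
}

write_pipeline_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_supermatrix_fasta(res$supermatrix,
                          file.path(dir, "supermatrix.fasta"))
  write_supermatrix_phylip(res$supermatrix,
                           file.path(dir, "supermatrix.phy"))
  write_partitions(res$supermatrix, file.path(dir, "partitions.txt"))
  readr::write_tsv(res$summary, file.path(dir, "summary.tsv"))
  readr::write_tsv(res$per_taxon_missing,
                   file.path(dir, "missing_per_taxon.tsv"))
  if (!is.null(res$diagnostics))
    readr::write_tsv(res$diagnostics, file.path(dir, "diagnostics.tsv"))
  readr::write_tsv(res$prune_report, file.path(dir, "prune_report.tsv"))
  readr::write_tsv(res$log, file.path(dir, "pipeline_log.tsv"))
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$manifest$stages)
  print(x$summary)
  invisible(x)
}
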