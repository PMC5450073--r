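# Seeded synthetic datasets with recorded ground truth: Yule species trees,
# duplication/loss gene trees, sequence alignments with optional long-branch
# taxa and compositional bias, and beta-law occupancy masks.  Every
# generator is a pure function of its arguments including the seed.

#' Synthetic dataset configuration
#'
#' Defaults emulate a transcriptome-scale phylogenomic study: 40 taxa,
#' 200 loci of 100-400 aligned amino acids, moderate gene duplication and
#' loss, one long-branch taxon with a 5x rate multiplier, a fifth of loci
#' compositionally biased in a three-taxon clade at intensity 0.5, and a
#' Beta(2, 1) per-locus taxon-retention law giving roughly a third missing
#' data.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param n_loci Number of loci (>= 1).
#' @param locus_length_range Min/max alignment columns per locus.
#' @param birth_rate Yule speciation rate (> 0).
#' @param duplication_rate,loss_rate Gene duplication/loss rates per unit
#'   branch length (>= 0).
#' @param long_branch_taxa Taxa whose terminal branches are rate-multiplied.
#' @param long_branch_multiplier Rate multiplier (> 1) for those taxa.
#' @param biased_taxa Taxa receiving compositional bias on biased loci.
#' @param bias_intensity Bias intensity in `[0, 1]`.
#' @param bias_target Length-20 target frequency vector (default
#'   [default_bias_target()]).
#' @param biased_loci_fraction Fraction of loci receiving the bias.
#' @param occupancy_alpha,occupancy_beta Beta-law parameters of the
#'   per-locus taxon-retention probability (> 0).
#' @param model Substitution model name for sequence simulation.
#' @param gene_tree_nni_moves Random NNI moves applied to each gene tree
#'   (gene-tree estimation noise; perturbed edges get Uniform(0,1)
#'   supports).
#' @param seed Integer seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_taxa = 40, n_loci = 200,
                             locus_length_range = c(100L, 400L),
                             birth_rate = 1, duplication_rate = 0.2,
                             loss_rate = 0.2,
                             long_branch_taxa = "t01",
                             long_branch_multiplier = 5,
                             biased_taxa = c("t02", "t03", "t04"),
                             bias_intensity = 0.5,
                             bias_target = default_bias_target(),
                             biased_loci_fraction = 0.2,
                             occupancy_alpha = 2, occupancy_beta = 1,
                             model = "WAG",
                             gene_tree_nni_moves = 0L,
                             seed = 1L) {
  stopifnot(n_taxa >= 2, n_loci >= 1,
            length(locus_length_range) == 2,
            locus_length_range[1] >= 1,
            locus_length_range[1] <= locus_length_range[2],
            birth_rate > 0, duplication_rate >= 0, loss_rate >= 0,
            long_branch_multiplier >= 1,
            bias_intensity >= 0, bias_intensity <= 1,
            length(bias_target) == 20, all(bias_target >= 0),
            biased_loci_fraction >= 0, biased_loci_fraction <= 1,
            occupancy_alpha > 0, occupancy_beta > 0,
            gene_tree_nni_moves >= 0)
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  stopifnot(all(long_branch_taxa %in% taxa), all(biased_taxa %in% taxa))
  structure(list(
    n_taxa = as.integer(n_taxa), n_loci = as.integer(n_loci), taxa = taxa,
    locus_length_range = as.integer(locus_length_range),
    birth_rate = birth_rate, duplication_rate = duplication_rate,
    loss_rate = loss_rate, long_branch_taxa = long_branch_taxa,
    long_branch_multiplier = long_branch_multiplier,
    biased_taxa = biased_taxa, bias_intensity = bias_intensity,
    bias_target = bias_target / sum(bias_target),
    biased_loci_fraction = biased_loci_fraction,
    occupancy_alpha = occupancy_alpha, occupancy_beta = occupancy_beta,
    model = model, gene_tree_nni_moves = as.integer(gene_tree_nni_moves),
    seed = as.integer(seed)), class = "synthetic_config")
}

#' Default compositional-bias target
#'
#' Puts half the equilibrium mass uniformly on A, G, P and S (a GC-rich
#' codon-bias analogue) and spreads the rest over the remaining residues in
#' proportion to the uniform distribution.
#'
#' @return Length-20 frequency vector summing to 1.
#' @export
default_bias_target <- function() {
  target <- rep(0.5 / 16, 20)
  target[match(c("A", "G", "P", "S"), AA_STATES)] <- 0.5 / 4
  target
}

#' Simulate a Yule species tree
#'
#' Pure-birth tree conditioned on `n_taxa` extant taxa, rescaled to unit
#' height (ultrametric).
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param birth_rate Speciation rate (> 0).
#' @param seed Integer seed.
#' @return A rooted ultrametric binary `phylo` with tips `t01, t02, ...`.
#' @export
simulate_species_tree <- function(n_taxa, birth_rate, seed) {
  stopifnot(n_taxa >= 2, birth_rate > 0)
  withr::with_seed(seed, simulate_species_tree_impl(n_taxa, birth_rate))
}

simulate_species_tree_impl <- function(n_taxa, birth_rate) {
  tr <- if (n_taxa == 2) {
    ape::read.tree(text = "(A:1,B:1);")
  } else {
    ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  }
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / h
  tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  tr$node.label <- NULL
  tr
}

# ---- gene-tree simulation (duplication/loss along the species tree) ----

# recursive birth-death of gene copies; returns a nested node list or NULL
# (all copies lost).  Each node: list(label, length, children, dup,
# original); `emit` is an environment tracking per-taxon copy counters and
# leaf records.
gene_node <- function(length, children = NULL, label = NULL, dup = FALSE,
                      original = FALSE) {
  list(label = label, length = length, children = children, dup = dup,
       original = original)
}

evolve_gene_branch <- function(sp, v, remaining, total_len, dup_rate,
                               loss_rate, original, emit) {
  rate <- dup_rate + loss_rate
  wait <- if (rate > 0) stats::rexp(1, rate) else Inf
  if (wait >= remaining) {
    # reach the end of this species branch
    ntip <- length(sp$tip.label)
    if (v <= ntip) {
      tax <- sp$tip.label[v]
      emit$counter[[tax]] <- (emit$counter[[tax]] %||% 0L) + 1L
      lab <- sprintf("%s|%d", tax, emit$counter[[tax]])
      emit$leaves[[length(emit$leaves) + 1L]] <-
        tibble::tibble(seq_id = lab, taxon = tax, original = original)
      return(gene_node(remaining, label = lab, original = original))
    }
    rows <- which(sp$edge[, 1] == v)
    kids <- list()
    for (ei in rows) {
      k <- evolve_gene_branch(sp, sp$edge[ei, 2], sp$edge.length[ei],
                              sp$edge.length[ei], dup_rate, loss_rate,
                              original, emit)
      if (!is.null(k)) kids[[length(kids) + 1L]] <- k
    }
    if (length(kids) == 0) return(NULL)
    if (length(kids) == 1) {
      kids[[1]]$length <- kids[[1]]$length + remaining
      return(kids[[1]])
    }
    return(gene_node(remaining, children = kids))
  }
  # an event happens after `wait`
  if (stats::runif(1) < loss_rate / rate) return(NULL)
  left <- evolve_gene_branch(sp, v, remaining - wait, total_len, dup_rate,
                             loss_rate, original, emit)
  right <- evolve_gene_branch(sp, v, remaining - wait, total_len, dup_rate,
                              loss_rate, FALSE, emit)
  if (is.null(left) && is.null(right)) return(NULL)
  if (is.null(left) || is.null(right)) {
    k <- if (is.null(left)) right else left
    k$length <- k$length + wait
    return(k)
  }
  gene_node(wait, children = list(left, right), dup = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gene_node_newick <- function(node) {
  if (is.null(node$children))
    return(sprintf("%s:%.10f", node$label, node$length))
  inner <- paste(vapply(node$children, gene_node_newick, character(1)),
                 collapse = ",")
  sprintf("(%s)1:%.10f", inner, node$length)
}

#' Simulate a gene tree inside a species tree
#'
#' Gene duplication and loss as independent Poisson processes along
#' species-tree branches; copies evolve independently after duplication.
#' Leaves are labelled `"taxon|copyN"`; taxa whose copies were all lost are
#' absent.  With `nni_moves > 0`, random NNI rearrangements emulate
#' gene-tree estimation error: edges still present in the undisturbed tree
#' keep support 1.0, perturbed edges get Uniform(0,1) supports.
#'
#' @param species_tree A rooted `phylo` (see [simulate_species_tree()]).
#' @param duplication_rate,loss_rate Event rates per unit branch length.
#' @param seed Integer seed.
#' @param nni_moves Number of random NNI moves (default 0).
#' @return A `phylo` with support node labels and attributes `leaf_truth`
#'   (tibble: `seq_id`, `taxon`, `original`) and `n_duplications`; `NULL`
#'   if every copy was lost.
#' @export
simulate_gene_tree <- function(species_tree, duplication_rate, loss_rate,
                               seed, nni_moves = 0L) {
  stopifnot(duplication_rate >= 0, loss_rate >= 0)
  withr::with_seed(seed, {
    simulate_gene_tree_impl(species_tree, duplication_rate, loss_rate,
                            nni_moves)
  })
}

count_dups <- function(node) {
  if (is.null(node$children)) return(0L)
  sum(vapply(node$children, count_dups, integer(1))) + as.integer(node$dup)
}

simulate_gene_tree_impl <- function(species_tree, duplication_rate,
                                    loss_rate, nni_moves = 0L) {
  sp <- ape::reorder.phylo(species_tree, "cladewise")
  root <- tree_root(sp)
  emit <- new.env()
  emit$counter <- list()
  emit$leaves <- list()
  # the root lineage starts above the species root with zero length
  node <- {
    rows <- which(sp$edge[, 1] == root)
    kids <- list()
    for (ei in rows) {
      k <- evolve_gene_branch(sp, sp$edge[ei, 2], sp$edge.length[ei],
                              sp$edge.length[ei], duplication_rate,
                              loss_rate, TRUE, emit)
      if (!is.null(k)) kids[[length(kids) + 1L]] <- k
    }
    if (length(kids) == 0) NULL
    else if (length(kids) == 1) kids[[1]]
    else gene_node(0, children = kids)
  }
  if (is.null(node)) return(NULL)
  truth <- dplyr::bind_rows(emit$leaves)
  if (nrow(truth) < 2) return(NULL)
  if (is.null(node$children)) return(NULL)  # single surviving leaf
  nwk <- sprintf("(%s);",
                 paste(vapply(node$children, gene_node_newick,
                              character(1)), collapse = ","))
  if (length(node$children) == 1)
    nwk <- sprintf("%s;", gene_node_newick(node$children[[1]]))
  tr <- ape::read.tree(text = nwk)
  n_dup <- count_dups(node)
  if (nni_moves > 0 && length(tr$tip.label) >= 4) {
    orig_bip <- edge_bipartitions(tr)
    for (i in seq_len(nni_moves)) {
      nbs <- nni_neighbors(tr)
      if (length(nbs) == 0) break
      tr <- nbs[[sample.int(length(nbs), 1)]]
    }
    new_bip <- edge_bipartitions(tr)
    lab <- vapply(new_bip, function(b) {
      if (is.na(b) || b %in% orig_bip) "1"
      else format(stats::runif(1), digits = 6)
    }, character(1))
    tr$node.label <- lab
  }
  attr(tr, "leaf_truth") <- truth
  attr(tr, "n_duplications") <- n_dup
  tr
}

# sorted-leafset strings for the clade below each internal node (NA for the
# root); used to recognise edges disturbed by NNI noise
edge_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge)))
    desc[[tree$edge[e, 1]]] <- c(desc[[tree$edge[e, 1]]],
                                 desc[[tree$edge[e, 2]]])
  root <- tree_root(tree)
  vapply((ntip + 1):max(tree$edge), function(v) {
    if (v == root) NA_character_
    else paste(sort(desc[[v]]), collapse = ";")
  }, character(1))
}

#' Simulate an alignment with rate and compositional heterogeneity
#'
#' Sequences are evolved along the gene tree under the model; terminal
#' branches of long-branch taxa are scaled by their multiplier, and biased
#' taxa evolve toward the mixed equilibrium
#' `(1 - b) * pi + b * bias_target` on their terminal branches.
#'
#' @param gene_tree A `phylo` with `taxon|copyN` leaf labels.
#' @param model An [aa_model()].
#' @param length Alignment columns (>= 1).
#' @param seed Integer seed.
#' @param rate_multipliers Named per-taxon terminal rate multipliers.
#' @param biased_taxa Taxa receiving compositional bias.
#' @param bias_target Length-20 target frequency vector.
#' @param bias_intensity Bias intensity `b` in `[0, 1]`.
#' @param bias_exposure Extra terminal evolution time under the biased
#'   regime (tree-height units, default 1); see [simulate_along_tree()].
#' @param locus_id Locus id of the resulting orthogroup.
#' @return An [orthogroup()].
#' @export
simulate_biased_alignment <- function(gene_tree, model, length, seed,
                                      rate_multipliers = NULL,
                                      biased_taxa = NULL,
                                      bias_target = default_bias_target(),
                                      bias_intensity = 0,
                                      bias_exposure = 1,
                                      locus_id = "locus") {
  stopifnot(length >= 1, bias_intensity >= 0, bias_intensity <= 1)
  if (!is.null(rate_multipliers)) stopifnot(all(rate_multipliers > 0))
  withr::with_seed(seed, {
    simulate_biased_alignment_impl(gene_tree, model, length,
                                   rate_multipliers, biased_taxa,
                                   bias_target, bias_intensity,
                                   bias_exposure, locus_id)
  })
}

simulate_biased_alignment_impl <- function(gene_tree, model, length,
                                           rate_multipliers = NULL,
                                           biased_taxa = NULL,
                                           bias_target =
                                             default_bias_target(),
                                           bias_intensity = 0,
                                           bias_exposure = 1,
                                           locus_id = "locus") {
  biased_freq <- NULL
  if (!is.null(biased_taxa) && bias_intensity > 0) {
    mix <- (1 - bias_intensity) * model$pi +
      bias_intensity * bias_target / sum(bias_target)
    biased_freq <- stats::setNames(
      rep(list(mix), base::length(biased_taxa)), biased_taxa)
  }
  sim_states_impl(gene_tree, model, length, locus_id = locus_id,
                  rate_multipliers = rate_multipliers,
                  biased_freq = biased_freq, bias_exposure = bias_exposure)
}

#' Apply a beta-law occupancy mask
#'
#' Per locus, a retention probability is drawn from
#' `Beta(occupancy_alpha, occupancy_beta)` and each taxon is independently
#' retained with that probability (all copies of a dropped taxon are
#' removed).  Loci left with fewer than two sequences are dropped.
#'
#' @param orthogroups List of [orthogroup()] objects.
#' @param occupancy_alpha,occupancy_beta Beta parameters (> 0).
#' @param seed Integer seed.
#' @return List with `orthogroups` (masked, non-empty loci) and `mask`
#'   (tibble: `locus_id`, `taxon`, `retained`).
#' @export
apply_occupancy_mask <- function(orthogroups, occupancy_alpha,
                                 occupancy_beta, seed) {
  stopifnot(occupancy_alpha > 0, occupancy_beta > 0)
  withr::with_seed(seed, {
    apply_occupancy_mask_impl(orthogroups, occupancy_alpha, occupancy_beta)
  })
}

apply_occupancy_mask_impl <- function(orthogroups, occupancy_alpha,
                                      occupancy_beta) {
  out <- list()
  mask_rows <- list()
  for (og in orthogroups) {
    taxa <- og_taxa(og)
    p <- stats::rbeta(1, occupancy_alpha, occupancy_beta)
    retained <- stats::runif(length(taxa)) <= p
    mask_rows[[length(mask_rows) + 1L]] <-
      tibble::tibble(locus_id = og$locus_id, taxon = taxa,
                     retained = retained)
    keep <- og$taxon %in% taxa[retained]
    if (sum(keep) >= 2)
      out[[length(out) + 1L]] <- og_subset(og, keep, drop_gap_cols = TRUE)
  }
  list(orthogroups = out, mask = dplyr::bind_rows(mask_rows))
}

#' Generate a complete synthetic dataset
#'
#' Species tree, per-locus duplication/loss gene trees, alignments with the
#' configured long-branch and compositional-bias structure, and an
#' occupancy mask, with full ground truth.  When `dir` is given, writes one
#' FASTA and one Newick file per surviving locus plus tab-separated truth
#' manifests.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory (created if needed).
#' @return List with `species_tree`, `orthogroups`, `gene_trees` (parallel
#'   lists for surviving loci), and `truth` (list: `loci` tibble with
#'   per-locus flags and status, `leaves` tibble with per-sequence origin
#'   and ortholog flags, `mask`, `config`).
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  res <- withr::with_seed(config$seed, generate_dataset_impl(config))
  if (!is.null(dir)) write_dataset(res, dir)
  res
}

generate_dataset_impl <- function(config) {
  sp <- simulate_species_tree_impl(config$n_taxa, config$birth_rate)
  model <- aa_model(config$model)
  lb_mult <- stats::setNames(rep(config$long_branch_multiplier,
                                 length(config$long_branch_taxa)),
                             config$long_branch_taxa)
  n_biased <- round(config$biased_loci_fraction * config$n_loci)
  biased_flags <- seq_len(config$n_loci) <= n_biased
  loci <- list(); trees <- list()
  locus_rows <- list(); leaf_rows <- list()
  for (i in seq_len(config$n_loci)) {
    id <- sprintf("OG%04d", i)
    gt <- simulate_gene_tree_impl(sp, config$duplication_rate,
                                  config$loss_rate,
                                  config$gene_tree_nni_moves)
    if (is.null(gt)) {
      locus_rows[[i]] <- tibble::tibble(
        locus_id = id, biased = biased_flags[i], status = "dropped_loss",
        n_duplications = NA_integer_)
      next
    }
    len <- config$locus_length_range[1] - 1L +
      sample.int(config$locus_length_range[2] -
                   config$locus_length_range[1] + 1L, 1)
    og <- simulate_biased_alignment_impl(
      gt, model, len,
      rate_multipliers = if (length(lb_mult)) lb_mult,
      biased_taxa = if (biased_flags[i]) config$biased_taxa,
      bias_target = config$bias_target,
      bias_intensity = if (biased_flags[i]) config$bias_intensity else 0,
      bias_exposure = 1, locus_id = id)
    loci[[id]] <- og
    trees[[id]] <- gt
    locus_rows[[i]] <- tibble::tibble(
      locus_id = id, biased = biased_flags[i], status = "kept",
      n_duplications = attr(gt, "n_duplications"))
    leaf_rows[[i]] <- dplyr::mutate(attr(gt, "leaf_truth"), locus_id = id,
                                    .before = 1)
  }
  masked <- apply_occupancy_mask_impl(loci, config$occupancy_alpha,
                                      config$occupancy_beta)
  kept_ids <- vapply(masked$orthogroups, function(o) o$locus_id,
                     character(1))
  locus_tbl <- dplyr::bind_rows(locus_rows)
  locus_tbl$status[locus_tbl$status == "kept" &
                     !(locus_tbl$locus_id %in% kept_ids)] <-
    "dropped_occupancy"
  gene_trees <- lapply(masked$orthogroups, function(og) {
    ape::keep.tip(trees[[og$locus_id]], og$seq_id)
  })
  leaves <- dplyr::bind_rows(leaf_rows)
  leaves <- dplyr::left_join(
    leaves, masked$mask,
    by = c("locus_id", "taxon"))
  leaves$retained[is.na(leaves$retained)] <- FALSE
  list(species_tree = sp, orthogroups = masked$orthogroups,
       gene_trees = gene_trees,
       truth = list(loci = locus_tbl, leaves = leaves, mask = masked$mask,
                    config = config))
}

write_dataset <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(res$orthogroups)) {
    og <- res$orthogroups[[i]]
    write_orthogroup(og, file.path(dir, paste0(og$locus_id, ".fasta")))
    write_gene_tree(res$gene_trees[[i]],
                    file.path(dir, paste0(og$locus_id, ".nwk")))
  }
  write_gene_tree(res$species_tree, file.path(dir, "species_tree.nwk"))
  readr::write_tsv(res$truth$loci, file.path(dir, "truth_loci.tsv"))
  readr::write_tsv(res$truth$leaves, file.path(dir, "truth_leaves.tsv"))
  invisible(dir)
}
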