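# ---- tree utilities ---------------------------------------------------

# numeric support values per internal node (NA where absent); validates range
node_supports <- function(tree) {
  ntip <- length(tree$tip.label)
  lab <- tree$node.label
  if (is.null(lab)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(lab))
  bad <- !is.na(sup) & (sup < 0 | sup > 1)
  if (any(bad))
    stop("support values outside [0, 1]: ", paste(sup[bad], collapse = ", "))
  length(sup) <- tree$Nnode
  sup
}

tree_root <- function(tree) {
  setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
}

# contract the edges above `nodes` (internal, non-root), reattaching their
# children to the nearest kept ancestor; contracted edge lengths are dropped
contract_internal_nodes <- function(tree, nodes) {
  if (length(nodes) == 0) return(tree)
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  root <- tree_root(tree)
  stopifnot(!root %in% nodes, all(nodes > ntip))
  parent_of <- integer(max(edge))
  parent_of[edge[, 2]] <- edge[, 1]
  resolve <- function(v) {
    while (v %in% nodes) v <- parent_of[v]
    v
  }
  keep <- !(edge[, 2] %in% nodes)
  new_edge <- cbind(vapply(edge[keep, 1], resolve, integer(1)),
                    edge[keep, 2])
  new_len <- tree$edge.length[keep]
  lab_orig <- tree$node.label
  kept_internal <- unique(new_edge[, 1])
  children <- split(seq_len(nrow(new_edge)), new_edge[, 1])
  # preorder renumbering: tips keep their ids, root becomes ntip + 1
  newid <- integer(max(edge))
  newid[seq_len(ntip)] <- seq_len(ntip)
  out_edge <- matrix(0L, nrow(new_edge), 2)
  out_len <- numeric(nrow(new_edge))
  out_lab <- character(length(kept_internal))
  counter <- ntip + 1L
  newid[root] <- counter
  if (!is.null(lab_orig)) out_lab[1] <- lab_orig[root - ntip]
  k <- 0L
  visit <- function(v) {
    for (ei in children[[as.character(v)]]) {
      child <- new_edge[ei, 2]
      k <<- k + 1L
      row <- k
      out_len[row] <<- new_len[ei]
      if (child <= ntip) {
        out_edge[row, ] <<- c(newid[v], child)
      } else {
        counter <<- counter + 1L
        newid[child] <<- counter
        if (!is.null(lab_orig))
          out_lab[counter - ntip] <<- lab_orig[child - ntip]
        out_edge[row, ] <<- c(newid[v], counter)
        visit(child)
      }
    }
  }
  visit(root)
  out <- list(edge = out_edge,
              edge.length = if (!is.null(tree$edge.length)) out_len,
              tip.label = tree$tip.label,
              Nnode = length(kept_internal))
  if (!is.null(lab_orig)) out$node.label <- out_lab
  out <- out[!vapply(out, is.null, logical(1))]
  structure(out, class = "phylo", order = "cladewise")
}

#' Collapse poorly supported branches into polytomies
#'
#' Contracts every internal edge whose support value is strictly below the
#' threshold (the default reproduces the usual `< 0.7` SH-like support
#' rule); edges with support exactly at the threshold, or with no support
#' value, are kept.  The leaf set is unchanged.
#'
#' @param tree A `phylo` gene tree; internal node labels hold supports in
#'   `[0, 1]` (may be absent).
#' @param threshold Support threshold in `[0, 1]` (default 0.7).
#' @return A `phylo`, possibly multifurcating.
#' @export
collapse_low_support <- function(tree, threshold = 0.7) {
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 3,
            threshold >= 0, threshold <= 1)
  sup <- node_supports(tree)
  ntip <- length(tree$tip.label)
  root <- tree_root(tree)
  nodes <- which(!is.na(sup) & sup < threshold) + ntip
  nodes <- setdiff(nodes, root)
  contract_internal_nodes(tree, nodes)
}

# ---- maximally inclusive subtree (tree-based paralog pruning) ----------

# leaf descendants of every node when the tree is rooted at `from`,
# entering via neighbor `start` (the cut edge being from--start);
# returns list(desc = list by node id, nodes = visited node ids)
oriented_desc <- function(adj, ntip, start, avoid) {
  desc <- vector("list", length(adj))
  visit <- function(v, parent) {
    if (v <= ntip) { desc[[v]] <<- v; return(v) }
    out <- integer(0)
    for (u in adj[[v]]) {
      if (u == parent) next
      out <- c(out, visit(u, v))
    }
    desc[[v]] <<- out
    out
  }
  visit(start, avoid)
  desc
}

adjacency <- function(tree) {
  n <- max(tree$edge)
  adj <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# validity of a candidate subtree: every taxon with > 1 leaf must be
# monophyletic within it, or have all its leaves attached to one node.
# For a subtree cut off at an edge the rooting is fixed by the cut; the
# whole tree is considered at all rootings, so monophyly there means an
# unrooted bipartition separating exactly the taxon's leaves.
candidate_valid <- function(desc, leaf_ids, taxon_of_leaf, adj,
                            unrooted = FALSE, all_leaves = NULL) {
  taxa <- taxon_of_leaf[as.character(leaf_ids)]
  for (t in unique(taxa[duplicated(taxa)])) {
    lt <- leaf_ids[taxa == t]
    # same-polytomy case: one shared neighbouring node
    parents <- vapply(lt, function(l) adj[[l]][1], integer(1))
    if (length(unique(parents)) == 1L) next
    present <- desc[!vapply(desc, is.null, logical(1))]
    if (unrooted) {
      split_found <- any(vapply(present, function(d) {
        setequal(d, lt) || setequal(setdiff(all_leaves, d), lt)
      }, logical(1)))
      if (!split_found) return(FALSE)
      next
    }
    # rooted monophyly: smallest clade containing lt has only taxon-t leaves
    cand <- Filter(function(d) all(lt %in% d), present)
    sizes <- vapply(cand, length, integer(1))
    mrca_desc <- cand[[which.min(sizes)]]
    if (!all(taxon_of_leaf[as.character(mrca_desc)] == t)) return(FALSE)
  }
  TRUE
}

#' Largest subtree with at most one sequence per taxon
#'
#' Scans every rooted subtree of the (unrooted, possibly multifurcating)
#' gene tree -- one per directed edge, plus the whole tree -- and returns
#' the one with the most leaves in which each taxon contributes at most one
#' sequence, except taxa whose sequences all form a clade or all attach to
#' the same polytomy (in-paralogs), which may contribute all of them.
#' Ties are broken by more distinct taxa, then greater total non-gap
#' residues (when an orthogroup is supplied), then the lexicographically
#' smallest leaf-label set.
#'
#' @param tree A `phylo`, typically the output of [collapse_low_support()].
#' @param taxon_map Named character vector mapping leaf labels to taxon ids;
#'   defaults to [taxon_from_id()] on the labels.
#' @param og Optional [orthogroup()] supplying residue counts for
#'   tie-breaking.
#' @param delim Delimiter for the default taxon extraction.
#' @return A list with `tree` (the retained subtree, `NULL` if unusable),
#'   `leaves`, `in_paralogs` (named list: taxon -> retained leaf labels) and
#'   `unusable` (fewer than 2 taxa retained).
#' @export
max_inclusive_subtree <- function(tree, taxon_map = NULL, og = NULL,
                                  delim = "|") {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (is.null(taxon_map))
    taxon_map <- stats::setNames(taxon_from_id(tree$tip.label, delim),
                                 tree$tip.label)
  taxon_of_leaf <- stats::setNames(unname(taxon_map[tree$tip.label]),
                                   as.character(seq_len(ntip)))
  residues <- if (!is.null(og)) {
    stats::setNames(og_residue_counts(og), og$seq_id)[tree$tip.label]
  } else stats::setNames(rep(0, ntip), tree$tip.label)
  adj <- adjacency(tree)
  root <- tree_root(tree)

  # candidates: (start, avoid) pairs; avoid = 0 means whole tree
  cand <- list(c(root, 0L))
  for (i in seq_len(nrow(tree$edge))) {
    cand[[length(cand) + 1L]] <- c(tree$edge[i, 2], tree$edge[i, 1])
    cand[[length(cand) + 1L]] <- c(tree$edge[i, 1], tree$edge[i, 2])
  }

  best <- NULL
  best_key <- NULL
  for (cd in cand) {
    desc <- oriented_desc(adj, ntip, cd[1], cd[2])
    leaves <- if (cd[1] <= ntip) cd[1] else desc[[cd[1]]]
    if (!candidate_valid(desc, leaves, taxon_of_leaf, adj,
                         unrooted = cd[2] == 0L,
                         all_leaves = seq_len(ntip))) next
    labels <- sort(tree$tip.label[leaves])
    key <- list(length(leaves),
                length(unique(taxon_of_leaf[as.character(leaves)])),
                sum(residues[tree$tip.label[leaves]]),
                labels)
    if (is.null(best_key) || candidate_better(key, best_key)) {
      best <- leaves
      best_key <- key
    }
  }
  leaves <- tree$tip.label[best]
  taxa <- taxon_of_leaf[as.character(best)]
  inpar <- split(leaves, taxa)
  inpar <- inpar[vapply(inpar, length, integer(1)) > 1]
  unusable <- length(unique(taxa)) < 2
  sub <- if (unusable || length(leaves) < 2) NULL
         else ape::keep.tip(tree, leaves)
  list(tree = sub, leaves = leaves, in_paralogs = inpar,
       unusable = unusable)
}

# TRUE if candidate key a beats b: more leaves, more taxa, more residues,
# then lexicographically smaller sorted label set
candidate_better <- function(a, b) {
  for (i in 1:3) {
    if (a[[i]] > b[[i]]) return(TRUE)
    if (a[[i]] < b[[i]]) return(FALSE)
  }
  la <- a[[4]]; lb <- b[[4]]
  n <- min(length(la), length(lb))
  for (i in seq_len(n)) {
    if (la[i] < lb[i]) return(TRUE)
    if (la[i] > lb[i]) return(FALSE)
  }
  FALSE
}

#' Prune an orthogroup to one putative ortholog per taxon
#'
#' The tree-based pruning stage: support values below the threshold are
#' collapsed into polytomies, the maximally inclusive subtree is selected
#' (see [max_inclusive_subtree()]), and within each retained in-paralog set
#' all but the longest sequence (most non-gap residues; ties broken by
#' sequence id) are deleted.  Columns are not realigned; all-gap columns are
#' dropped.
#'
#' @param og An [orthogroup()].
#' @param tree The gene tree for the locus; leaf labels must match sequence
#'   ids in `og`.
#' @param threshold Support threshold (default 0.7; strictly lower supports
#'   collapse).
#' @param delim Taxon delimiter within sequence ids.
#' @return The pruned [orthogroup()] (at most one record per taxon), with a
#'   `report` attribute (one-row tibble: leaves in/out, in-paralogs
#'   collapsed, taxa retained, unusable flag).
#' @export
prune_orthogroup <- function(og, tree, threshold = 0.7, delim = "|") {
  stopifnot(inherits(og, "orthogroup"), inherits(tree, "phylo"))
  missing <- setdiff(tree$tip.label, og$seq_id)
  if (length(missing))
    stop("gene-tree leaves absent from orthogroup: ",
         paste(missing, collapse = ", "))
  taxon_map <- stats::setNames(og$taxon, og$seq_id)[tree$tip.label]
  names(taxon_map) <- tree$tip.label
  collapsed <- if (length(tree$tip.label) >= 3)
    collapse_low_support(tree, threshold) else tree
  sel <- max_inclusive_subtree(collapsed, taxon_map = taxon_map, og = og,
                               delim = delim)
  res <- og_residue_counts(og)
  names(res) <- og$seq_id
  keep <- setdiff(sel$leaves, unlist(lapply(sel$in_paralogs, function(x) x)))
  n_collapsed <- 0L
  for (grp in sel$in_paralogs) {
    ord <- order(-res[grp], grp)
    keep <- c(keep, grp[ord[1]])
    n_collapsed <- n_collapsed + length(grp) - 1L
  }
  if (sel$unusable) keep <- character(0)
  # original record order, so that re-pruning is a fixed point
  out <- og_subset(og, sort(match(keep, og$seq_id)), drop_gap_cols = TRUE)
  attr(out, "report") <- tibble::tibble(
    locus_id = og$locus_id,
    leaves_in = length(tree$tip.label),
    leaves_out = length(keep),
    in_paralogs_collapsed = n_collapsed,
    taxa_retained = length(unique(out$taxon)),
    unusable = sel$unusable)
  out
}

# ---- occupancy filtering ----------------------------------------------

#' Minimum taxon count implied by an occupancy fraction
#'
#' The smallest integer greater than or equal to `fraction * n_total_taxa`:
#' at 75% of 40 taxa a locus needs 30 taxa; at 50% of 37 it needs 19.
#'
#' @param fraction Occupancy fraction in `(0, 1]`.
#' @param n_total_taxa Total number of taxa in the study.
#' @return Integer minimum taxon count.
#' @export
min_taxa_required <- function(fraction, n_total_taxa) {
  stopifnot(fraction > 0, fraction <= 1, n_total_taxa >= 1)
  as.integer(ceiling(fraction * n_total_taxa))
}

#' Filter loci by gene occupancy
#'
#' Retains orthogroups whose distinct-taxon count is at least
#' `ceiling(fraction * n_total_taxa)`.
#'
#' @param orthogroups List of [orthogroup()] objects.
#' @param fraction Occupancy fraction in `(0, 1]`.
#' @param n_total_taxa Total number of taxa sampled in the study.
#' @return List with `orthogroups` (the retained loci), `min_taxa`, and
#'   `report` (tibble: locus, taxon count, retained flag).
#' @export
occupancy_filter <- function(orthogroups, fraction, n_total_taxa) {
  min_taxa <- min_taxa_required(fraction, n_total_taxa)
  counts <- vapply(orthogroups, function(o) length(og_taxa(o)), integer(1))
  keep <- counts >= min_taxa
  list(orthogroups = orthogroups[keep],
       min_taxa = min_taxa,
       report = tibble::tibble(
         locus_id = vapply(orthogroups, function(o) o$locus_id,
                           character(1)),
         n_taxa = counts, retained = keep))
}

#' Remove duplicated records within taxa
#'
#' Records with identical taxon and identical residues are collapsed to
#' one, keeping the first-encountered sequence id; record order is
#' otherwise preserved.  Identical residues in different taxa are kept.
#'
#' @param og An [orthogroup()].
#' @return An [orthogroup()].
#' @export
dedupe_records <- function(og) {
  key <- paste(og$taxon, apply(og$mat, 1, paste, collapse = ""),
               sep = "\r")
  og_subset(og, !duplicated(key))
}
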