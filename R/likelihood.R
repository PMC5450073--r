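# Small-scale amino-acid phylogenetic likelihood: Felsenstein pruning under
# empirical exchangeability matrices with discrete-gamma rates.  The
# per-site kernel lives in src/pruning.cpp; this file prepares data
# (pattern compression, tip encoding), and implements distance estimation,
# NJ starting trees, branch-length optimization, constraint-aware NNI
# search, model selection and sequence simulation.

# one-row-per-taxon character matrix from an orthogroup or supermatrix
aln_taxa_matrix <- function(alignment) {
  if (inherits(alignment, "supermatrix")) return(alignment$mat)
  stopifnot(inherits(alignment, "orthogroup"))
  if (anyDuplicated(alignment$taxon))
    stop("alignment has more than one sequence per taxon; prune first")
  mat <- alignment$mat
  rownames(mat) <- alignment$taxon
  mat
}

# integer tip states (0 = ambiguous) and site-pattern compression
encode_alignment <- function(mat, compress = TRUE) {
  ints <- matrix(match(mat, AA_STATES, nomatch = 0L), nrow = nrow(mat),
                 dimnames = dimnames(mat))
  if (ncol(ints) == 0)
    stop("alignment has no columns")
  if (!compress)
    return(list(states = ints, weights = rep(1, ncol(ints))))
  key <- apply(ints, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  list(states = ints[, first, drop = FALSE], weights = w)
}

# assemble kernel arguments for a tree/alignment/model triple
kernel_args <- function(tree, alignment, model, compress = TRUE) {
  mat <- aln_taxa_matrix(alignment)
  if (!setequal(tree$tip.label, rownames(mat)))
    stop("tree leaves and alignment taxa do not match")
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths")
  tree <- ape::reorder.phylo(tree, "postorder")
  enc <- encode_alignment(mat[tree$tip.label, , drop = FALSE], compress)
  rc <- model_rates(model)
  list(edge = tree$edge, el = tree$edge.length,
       ntip = length(tree$tip.label), states = enc$states,
       weights = enc$weights, V = model$V, Vinv = model$Vinv,
       lam = model$lambda, pi = model$pi, rates = rc$rates,
       rw = rc$weights, tree = tree)
}

#' Phylogenetic log-likelihood
#'
#' Site log-likelihoods by Felsenstein pruning, averaged over discrete-gamma
#' rate categories and summed over sites.  Gaps and ambiguity codes are
#' fully ambiguous; identical site patterns share computation unless
#' `compress = FALSE`.
#'
#' @param tree A `phylo` with branch lengths; leaves must match the
#'   alignment taxa.
#' @param alignment An [orthogroup()] (at most one sequence per taxon) or a
#'   supermatrix.
#' @param model An [aa_model()].
#' @param compress Use site-pattern compression (default `TRUE`).
#' @return Log-likelihood (scalar).
#' @examples
#' og <- orthogroup("x", c("A", "B"), c("A", "B"), c("MK", "MK"))
#' tr <- ape::read.tree(text = "(A:0,B:0);")
#' log_likelihood(tr, og, aa_model("Poisson")) # = 2 * log(1/20)
#' @export
log_likelihood <- function(tree, alignment, model, compress = TRUE) {
  ka <- kernel_args(tree, alignment, model, compress)
  .pruning_lnl(ka$edge, ka$el, ka$ntip, ka$states, ka$weights, ka$V,
               ka$Vinv, ka$lam, ka$pi, ka$rates, ka$rw)
}

#' Pairwise maximum-likelihood distances
#'
#' One-dimensional optimisation of the two-sequence likelihood for each
#' taxon pair; pairs with no shared unambiguous sites get the cap with a
#' warning.
#'
#' @param alignment An [orthogroup()] or supermatrix.
#' @param model An [aa_model()] (rate categories are ignored here).
#' @param max_dist Cap for saturated pairs (default 10).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
estimate_distances <- function(alignment, model, max_dist = 10) {
  mat <- aln_taxa_matrix(alignment)
  ints <- matrix(match(mat, AA_STATES, nomatch = 0L), nrow = nrow(mat))
  n <- nrow(mat)
  stopifnot(n >= 2)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  logpi <- log(model$pi)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- ints[i, ] > 0 & ints[j, ] > 0
      if (!any(ok)) {
        warning("no shared unambiguous sites for pair ", rownames(mat)[i],
                "/", rownames(mat)[j], "; distance capped")
        d[i, j] <- d[j, i] <- max_dist
        next
      }
      a <- ints[i, ok]; b <- ints[j, ok]
      if (all(a == b)) next
      C <- matrix(tabulate(a + 20L * (b - 1L), nbins = 400L), 20, 20)
      nll <- function(t) {
        P <- transition_prob(model, t)
        lp <- log(pmax(P, 1e-300)) + logpi
        -sum(C * lp)
      }
      opt <- stats::optimize(nll, c(1e-9, max_dist), tol = 1e-8)
      d[i, j] <- d[j, i] <- min(opt$minimum, max_dist)
    }
  }
  d
}

#' Neighbour-joining tree
#'
#' Standard NJ agglomeration ([ape::nj()]) with negative branch lengths
#' clamped to zero.
#'
#' @param distances Symmetric distance matrix, n >= 3.
#' @return An unrooted `phylo`.
#' @export
nj_tree <- function(distances) {
  stopifnot(nrow(distances) >= 3)
  tr <- ape::nj(as.dist(distances))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Optimise branch lengths
#'
#' Iterative one-branch-at-a-time optimisation (golden-section on each
#' edge, with the rest of the tree held fixed) until a sweep improves the
#' log-likelihood by less than `tol`.  The reported per-sweep
#' log-likelihood sequence is non-decreasing.
#'
#' @param tree A `phylo` with (starting) branch lengths.
#' @param alignment An [orthogroup()] or supermatrix.
#' @param model An [aa_model()].
#' @param max_sweeps Maximum optimisation sweeps (default 25).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-4).
#' @param min_branch,max_branch Box constraints for branch lengths.
#' @return The tree with optimised lengths; attributes `loglik` (scalar),
#'   `trace` (per-sweep log-likelihoods) and `converged` (logical; `FALSE`
#'   means the sweep budget was exhausted and the best-so-far is returned).
#' @export
optimize_branch_lengths <- function(tree, alignment, model,
                                    max_sweeps = 25, tol = 1e-4,
                                    min_branch = 1e-8, max_branch = 10) {
  mat <- aln_taxa_matrix(alignment)
  if (!setequal(tree$tip.label, rownames(mat)))
    stop("tree leaves and alignment taxa do not match")
  enc <- encode_alignment(mat)
  fit_edges(tree, enc, model, max_sweeps = max_sweeps, tol = tol,
            min_branch = min_branch, max_branch = max_branch)
}

# branch-length optimisation against a pre-encoded alignment; `enc` comes
# from encode_alignment() with taxon rownames
fit_edges <- function(tree, enc, model, max_sweeps = 25, tol = 1e-4,
                      iter = 28L, min_branch = 1e-8, max_branch = 10,
                      warn = TRUE) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  tree <- ape::reorder.phylo(tree, "postorder")
  rc <- model_rates(model)
  fit <- .optim_edges(tree$edge, tree$edge.length,
                      length(tree$tip.label),
                      enc$states[tree$tip.label, , drop = FALSE],
                      enc$weights, model$V, model$Vinv, model$lambda,
                      model$pi, rc$rates, rc$weights,
                      as.integer(max_sweeps), tol, min_branch, max_branch,
                      as.integer(iter))
  out <- tree
  out$edge.length <- as.numeric(fit$el)
  attr(out, "loglik") <- fit$loglik
  attr(out, "trace") <- as.numeric(fit$trace)
  attr(out, "converged") <- fit$converged
  if (warn && !fit$converged)
    warning("branch-length optimisation did not converge; ",
            "returning best tree so far")
  out
}

# optimise the gamma shape on a fixed tree (bounded 1-D search)
fit_gamma_shape <- function(tree, alignment, model,
                            interval = c(0.05, 50)) {
  f <- function(a) {
    m <- model
    m$alpha <- a
    -log_likelihood(tree, alignment, m)
  }
  opt <- stats::optimize(f, interval, tol = 1e-3)
  model$alpha <- opt$minimum
  model
}

#' Nearest-neighbour-interchange neighbours
#'
#' All trees one NNI move away from an unrooted binary tree (two per
#' internal edge); branch lengths are carried over unchanged.
#'
#' @param tree An unrooted `phylo` with branch lengths.
#' @return List of `phylo` objects.
#' @export
nni_neighbors <- function(tree) {
  tree <- ape::reorder.phylo(ape::unroot(tree))
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  res <- list()
  for (ei in which(edge[, 2] > ntip)) {
    u <- edge[ei, 1]; v <- edge[ei, 2]
    sib_rows <- setdiff(which(edge[, 1] == u), ei)
    if (length(sib_rows) == 0) next
    s_row <- sib_rows[1]
    for (c_row in which(edge[, 1] == v)) {
      e2 <- edge
      e2[s_row, 1] <- v
      e2[c_row, 1] <- u
      nb <- list(edge = e2, edge.length = tree$edge.length,
                 tip.label = tree$tip.label, Nnode = tree$Nnode)
      class(nb) <- "phylo"
      res[[length(res) + 1L]] <- ape::reorder.phylo(nb)
    }
  }
  res
}

# constraint-compatible NJ start: constrained taxa grafted as a clade
constrained_start <- function(d, constraint, min_branch = 1e-8) {
  labs <- rownames(d)
  outs <- setdiff(labs, constraint)
  din <- d[constraint, constraint, drop = FALSE]
  t_in <- if (length(constraint) == 2) {
    ape::read.tree(text = sprintf("(%s:%f,%s:%f);", constraint[1],
                                  din[1, 2] / 2, constraint[2],
                                  din[1, 2] / 2))
  } else {
    nj_tree(din)
  }
  ph <- "..constraint.."
  dp <- rbind(cbind(d[outs, outs, drop = FALSE],
                    rowMeans(d[outs, constraint, drop = FALSE])),
              c(colMeans(d[constraint, outs, drop = FALSE]), 0))
  rownames(dp) <- colnames(dp) <- c(outs, ph)
  t_out <- if (length(outs) >= 2) nj_tree(dp) else NULL
  if (is.null(t_out)) {
    # one outside taxon: attach it to the constraint subtree directly
    tr <- ape::bind.tree(
      ape::read.tree(text = sprintf("(%s:%f,%s:0);", outs, 1, ph)),
      t_in, where = 2)
  } else {
    tr <- ape::bind.tree(t_out, t_in,
                         where = which(t_out$tip.label == ph))
  }
  tr <- ape::unroot(tr)
  tr$edge.length[is.na(tr$edge.length) | tr$edge.length < min_branch] <-
    min_branch
  tr
}

#' Maximum-likelihood tree search
#'
#' Neighbour-joining start (constraint-compatible when a monophyly
#' constraint is given) followed by NNI hill-climbing with branch-length
#' re-optimisation; moves violating the constraint are rejected.
#'
#' @param alignment An [orthogroup()] or supermatrix with >= 4 taxa.
#' @param model An [aa_model()].
#' @param constraint Optional character vector of taxa (>= 2) required to be
#'   monophyletic.
#' @param max_rounds Maximum NNI improvement rounds (default 20).
#' @param quick_sweeps Branch-length sweeps used to score candidate
#'   neighbours (default 1; the accepted tree is re-optimised fully).
#' @param tol Improvement threshold for accepting a neighbour.
#' @return List with `tree` (optimised `phylo`) and `loglik`.
#' @export
ml_search <- function(alignment, model, constraint = NULL, max_rounds = 20,
                      quick_sweeps = 1, tol = 1e-6) {
  mat <- aln_taxa_matrix(alignment)
  if (nrow(mat) < 4) stop("ml_search needs at least 4 taxa")
  if (!is.null(constraint)) {
    if (!all(constraint %in% rownames(mat)))
      stop("constraint taxa missing from alignment")
    stopifnot(length(constraint) >= 2)
  }
  d <- estimate_distances(alignment, model)
  enc <- encode_alignment(mat)
  ml_search_impl(d, enc, model, constraint, max_rounds, quick_sweeps, tol)
}

# search core reusing precomputed distances and encoded alignment
ml_search_impl <- function(d, enc, model, constraint = NULL,
                           max_rounds = 20, quick_sweeps = 1, tol = 1e-6) {
  start <- nj_tree(d)
  start$edge.length[start$edge.length < 1e-8] <- 1e-8
  if (!is.null(constraint) && !is_monophyletic(start, constraint))
    start <- constrained_start(d, constraint)
  cur <- fit_edges(start, enc, model)
  cur_lnl <- attr(cur, "loglik")
  for (round in seq_len(max_rounds)) {
    nbs <- nni_neighbors(cur)
    if (!is.null(constraint))
      nbs <- Filter(function(t) is_monophyletic(t, constraint), nbs)
    if (length(nbs) == 0) break
    # quick partial optimisation gives a lower bound on each neighbour's
    # optimum, so accepting only improvements keeps the climb monotone
    scores <- vapply(nbs, function(nb) {
      attr(fit_edges(nb, enc, model, max_sweeps = quick_sweeps,
                     iter = 14L, warn = FALSE), "loglik")
    }, numeric(1))
    best <- which.max(scores)
    if (scores[best] <= cur_lnl + tol) break
    cur <- fit_edges(nbs[[best]], enc, model)
    cur_lnl <- attr(cur, "loglik")
  }
  list(tree = cur, loglik = cur_lnl)
}

#' Select the best-fitting substitution model
#'
#' Scores each candidate by log-likelihood on a shared NJ tree (built from
#' Poisson-model distances) with branch lengths re-optimised per model;
#' highest log-likelihood wins, ties broken by candidate order.
#'
#' @param alignment An [orthogroup()] or supermatrix with >= 3 taxa.
#' @param candidates Character vector of model names (default all four).
#' @return List with `model` (the winning name), and `scores` (tibble of
#'   per-candidate log-likelihoods).
#' @export
select_model <- function(alignment,
                         candidates = c("Poisson", "JTT", "WAG", "LG")) {
  if (length(candidates) == 0) stop("empty candidate list")
  mat <- aln_taxa_matrix(alignment)
  stopifnot(nrow(mat) >= 3)
  base <- nj_tree(estimate_distances(alignment, aa_model("Poisson")))
  base$edge.length[base$edge.length < 1e-8] <- 1e-8
  enc <- encode_alignment(mat)
  lnl <- vapply(candidates, function(nm) {
    attr(fit_edges(base, enc, aa_model(nm), warn = FALSE), "loglik")
  }, numeric(1))
  list(model = candidates[which.max(lnl)],
       scores = tibble::tibble(model = candidates, loglik = unname(lnl)))
}

#' Simulate sequences along a tree
#'
#' Root states are drawn from the model's equilibrium frequencies and
#' evolved along branches via the transition probabilities; with gamma rate
#' variation a rate category is drawn per site.  Deterministic given the
#' seed.
#'
#' @param tree A `phylo` with branch lengths.
#' @param model An [aa_model()].
#' @param length Number of alignment columns (>= 1).
#' @param seed Integer seed.
#' @param locus_id Locus id for the resulting orthogroup.
#' @param rate_multipliers Optional named vector of per-taxon terminal
#'   branch-length multipliers.
#' @param biased_freq Optional list mapping taxon id to a length-20
#'   frequency vector: the taxon's terminal branch evolves toward that
#'   equilibrium instead of the model's, for the branch itself plus
#'   `bias_exposure` extra time under the biased regime.
#' @param bias_exposure Extra terminal evolution time (in tree-height
#'   units) under the biased equilibrium for biased taxa (default 1).
#' @param delim Taxon/copy delimiter used to interpret leaf labels.
#' @return An [orthogroup()] with one record per leaf.
#' @export
simulate_along_tree <- function(tree, model, length, seed,
                                locus_id = "locus", rate_multipliers = NULL,
                                biased_freq = NULL, bias_exposure = 1,
                                delim = "|") {
  stopifnot(length >= 1)
  withr::with_seed(seed, {
    sim_states_impl(tree, model, length, locus_id, rate_multipliers,
                    biased_freq, bias_exposure, delim)
  })
}

# RNG-using core of simulate_along_tree (callers manage seeding)
sim_states_impl <- function(tree, model, length, locus_id = "locus",
                            rate_multipliers = NULL, biased_freq = NULL,
                            bias_exposure = 1, delim = "|") {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  ntip <- base::length(tree$tip.label)
  nnode <- max(tree$edge)
  rc <- model_rates(model)
  k <- base::length(rc$rates)
  cat_of_site <- if (k == 1) rep(1L, length)
                 else sample.int(k, length, replace = TRUE,
                                 prob = rc$weights)
  states <- matrix(0L, nnode, length)
  root <- tree_root(tree)
  states[root, ] <- sample.int(20, length, replace = TRUE, prob = model$pi)
  taxa <- taxon_from_id(tree$tip.label, delim)
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    t_e <- tree$edge.length[e]
    m_e <- model
    if (v <= ntip) {
      tax <- taxa[v]
      if (!is.null(rate_multipliers) && tax %in% names(rate_multipliers))
        t_e <- t_e * rate_multipliers[[tax]]
      if (!is.null(biased_freq) && tax %in% names(biased_freq)) {
        m_e <- aa_model(model$name, freq = biased_freq[[tax]],
                        alpha = model$alpha, n_rate_categories = model$k)
        # the lineage has spent `bias_exposure` extra time under the
        # biased regime on top of its terminal branch
        t_e <- t_e + bias_exposure
      }
    }
    for (c in seq_len(k)) {
      idx <- which(cat_of_site == c)
      if (!base::length(idx)) next
      P <- transition_prob(m_e, t_e * rc$rates[c])
      ps <- states[u, idx]
      for (s in unique(ps)) {
        sel <- idx[ps == s]
        states[v, sel] <- sample.int(20, base::length(sel),
                                     replace = TRUE, prob = P[s, ])
      }
    }
  }
  mat <- matrix(AA_STATES[states[seq_len(ntip), , drop = FALSE]],
                nrow = ntip)
  rownames(mat) <- tree$tip.label
  orthogroup(locus_id, taxa, tree$tip.label, mat)
}
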