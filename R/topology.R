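#' Test monophyly of a taxon set on an unrooted tree
#'
#' TRUE iff some edge of the (unrooted) tree splits exactly `taxa` from the
#' rest; the full leaf set is monophyletic by convention (the trivial
#' bipartition).
#'
#' @param tree A `phylo`.
#' @param taxa Character vector of leaf labels, length >= 2.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"), length(taxa) >= 2)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (setequal(taxa, tree$tip.label)) return(TRUE)
  ntip <- length(tree$tip.label)
  target <- sort(match(unique(taxa), tree$tip.label))
  tree <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    desc[[u]] <- c(desc[[u]], desc[[v]])
  }
  all_leaves <- seq_len(ntip)
  for (e in seq_len(nrow(tree$edge))) {
    side <- sort(desc[[tree$edge[e, 2]]])
    if (identical(side, target)) return(TRUE)
    if (identical(sort(setdiff(all_leaves, side)), target)) return(TRUE)
  }
  FALSE
}

#' SOWH parametric-bootstrap topology test
#'
#' Compares the unconstrained maximum-likelihood tree with the best tree
#' constrained to keep `constraint` monophyletic.  The test statistic is
#' `delta = lnL(unconstrained) - lnL(constrained)`, floored at zero (nested
#' hypotheses).  The null distribution is built by simulating `n_sim` data
#' sets of the observed length on the constrained ML tree with its fitted
#' parameters and re-running both searches on each.  The p-value is the
#' proportion of simulated deltas at least as large as the observed one
#' (optionally the `(k + 1) / (n + 1)` variant), with a Clopper-Pearson
#' binomial confidence interval recorded after every replicate.
#'
#' @param alignment An [orthogroup()] or supermatrix (>= 4 taxa).
#' @param model An [aa_model()].
#' @param constraint Character vector of taxa (>= 2) forced monophyletic
#'   under the null hypothesis.
#' @param n_sim Number of parametric-bootstrap replicates (default 100).
#' @param seed Integer seed driving all simulation randomness.
#' @param refit_alpha Re-fit the gamma shape on the constrained tree before
#'   simulating (only when the model has gamma rates; default `TRUE`).
#' @param p_formula `"proportion"` (`k / n`) or `"plus_one"`
#'   (`(k + 1) / (n + 1)`).
#' @param conf_level Confidence level for the Clopper-Pearson interval.
#' @return An object of class `sowh_result`.
#' @export
sowh_test <- function(alignment, model, constraint, n_sim = 100, seed = 1,
                      refit_alpha = TRUE,
                      p_formula = c("proportion", "plus_one"),
                      conf_level = 0.95) {
  p_formula <- match.arg(p_formula)
  stopifnot(n_sim >= 1)
  mat <- aln_taxa_matrix(alignment)
  d_obs <- estimate_distances(alignment, model)
  enc_obs <- encode_alignment(mat)
  unc <- ml_search_impl(d_obs, enc_obs, model)
  con <- ml_search_impl(d_obs, enc_obs, model, constraint = constraint)
  delta_raw <- unc$loglik - con$loglik
  if (delta_raw < -1e-3)
    warning(sprintf("negative observed delta (%.4g) floored at 0; %s",
                    delta_raw, "optimizer noise"))
  delta_obs <- max(0, delta_raw)

  sim_model <- model
  if (!is.null(model$alpha) && refit_alpha)
    sim_model <- fit_gamma_shape(con$tree, alignment, model)
  len <- ncol(aln_taxa_matrix(alignment))
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_sim))

  deltas <- numeric(n_sim)
  seq_rows <- vector("list", n_sim)
  for (i in seq_len(n_sim)) {
    sim <- simulate_along_tree(con$tree, sim_model, len, seeds[i],
                               locus_id = sprintf("sowh_sim_%03d", i))
    d_i <- estimate_distances(sim, model)
    enc_i <- encode_alignment(aln_taxa_matrix(sim))
    u_i <- ml_search_impl(d_i, enc_i, model)
    c_i <- ml_search_impl(d_i, enc_i, model, constraint = constraint)
    deltas[i] <- max(0, u_i$loglik - c_i$loglik)
    k <- sum(deltas[seq_len(i)] >= delta_obs)
    ci <- stats::binom.test(k, i, conf.level = conf_level)$conf.int
    seq_rows[[i]] <- tibble::tibble(
      replicate = i, delta_sim = deltas[i],
      p_value = p_estimate(k, i, p_formula),
      ci_low = ci[1], ci_high = ci[2])
  }
  sequential <- dplyr::bind_rows(seq_rows)
  k <- sum(deltas >= delta_obs)
  ci <- stats::binom.test(k, n_sim, conf.level = conf_level)$conf.int
  structure(
    list(delta_observed = delta_obs, simulated_deltas = deltas,
         n_sim = n_sim, p_value = p_estimate(k, n_sim, p_formula),
         ci_low = ci[1], ci_high = ci[2], sequential = sequential,
         seed = seed, constraint = constraint,
         unconstrained = unc, constrained = con,
         p_formula = p_formula, conf_level = conf_level),
    class = "sowh_result")
}

p_estimate <- function(k, n, p_formula) {
  if (p_formula == "plus_one") (k + 1) / (n + 1) else k / n
}

#' @export
print.sowh_result <- function(x, ...) {
  cat("SOWH parametric bootstrap test\n")
  cat(sprintf("  constraint: monophyly of {%s}\n",
              paste(x$constraint, collapse = ", ")))
  cat(sprintf("  observed delta = %.4f\n", x$delta_observed))
  cat(sprintf("  p = %.4g (%d simulations, %.0f%% CI %.4g-%.4g)\n",
              x$p_value, x$n_sim, 100 * x$conf_level, x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.sowh_result <- function(x, ...) x$sequential

#' @export
glance.sowh_result <- function(x, ...) {
  tibble::tibble(delta_observed = x$delta_observed, n_sim = x$n_sim,
                 p_value = x$p_value, ci_low = x$ci_low,
                 ci_high = x$ci_high,
                 lnl_unconstrained = x$unconstrained$loglik,
                 lnl_constrained = x$constrained$loglik)
}

#' Null-distribution plot for a SOWH test
#'
#' @param object A `sowh_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sowh_result <- function(object, ...) {
  df <- tibble::tibble(delta = object$simulated_deltas)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = object$delta_observed,
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = expression(delta[sim]),
                  y = "count",
                  title = sprintf("observed delta = %.3f, p = %.3g",
                                  object$delta_observed, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Posterior model odds from a tree sample
#'
#' Divides the frequency of post-burn-in trees supporting one topological
#' hypothesis by the frequency supporting the alternative.  Trees resolving
#' neither hypothesis are counted separately.
#'
#' @param tree_sample A `multiPhylo` or list of `phylo` trees.
#' @param h1,h2 Predicates: functions of a tree returning TRUE/FALSE (see
#'   [monophyly_of()] and [not_monophyly_of()]).
#' @return An object of class `posterior_odds` with counts and `odds`
#'   (`Inf` when only h1 is supported).
#' @export
posterior_model_odds <- function(tree_sample, h1, h2) {
  stopifnot(length(tree_sample) >= 1, is.function(h1), is.function(h2))
  s1 <- vapply(tree_sample, h1, logical(1))
  s2 <- vapply(tree_sample, h2, logical(1))
  n1 <- sum(s1); n2 <- sum(s2)
  if (n1 == 0 && n2 == 0)
    stop("no trees in the sample support either hypothesis; odds undefined")
  odds <- if (n2 == 0) Inf else n1 / n2
  structure(list(n_trees = length(tree_sample), n_support_h1 = n1,
                 n_support_h2 = n2,
                 n_neither = length(tree_sample) - n1 - n2, odds = odds),
            class = "posterior_odds")
}

#' @export
print.posterior_odds <- function(x, ...) {
  cat(sprintf(
    "posterior model odds = %s (h1: %d, h2: %d, neither: %d of %d trees)\n",
    format(x$odds), x$n_support_h1, x$n_support_h2, x$n_neither,
    x$n_trees))
  invisible(x)
}

#' Monophyly predicates for posterior model odds
#'
#' @param taxa Character vector of leaf labels (>= 2).
#' @return A function of a tree returning TRUE/FALSE.
#' @export
monophyly_of <- function(taxa) {
  force(taxa)
  function(tree) is_monophyletic(tree, taxa)
}

#' @rdname monophyly_of
#' @export
not_monophyly_of <- function(taxa) {
  force(taxa)
  function(tree) !is_monophyletic(tree, taxa)
}
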