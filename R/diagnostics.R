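# Per-locus branch-length and compositional heterogeneity screening.
#
# Branch-length indices follow the TreSpEx definitions: average patristic
# distance, standard deviation of the tip-to-root distance, and the LB
# score (percentage deviation of a taxon's mean pairwise patristic distance
# from the tree-wide mean).  Compositional indices follow BaCoCa: RCFV and
# a chi-square test of residue-composition homogeneity across taxa.

#' Patristic distance matrix
#'
#' Sum of branch lengths along the tree path between every pair of leaves.
#'
#' @param tree A `phylo` with branch lengths.
#' @return Symmetric numeric matrix with zero diagonal, labelled by leaf.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 2)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have complete branch lengths")
  ape::cophenetic.phylo(tree)
}

#' Per-taxon LB scores
#'
#' `LB_i = 100 * (meanPD_i / grand_mean_PD - 1)` where `meanPD_i` is the
#' mean patristic distance from taxon i to all other taxa and the grand
#' mean is over all ordered pairs.  LB scores always average to zero across
#' taxa.
#'
#' @param tree A `phylo` with branch lengths and at least 3 leaves.
#' @return Named numeric vector of LB scores.
#' @export
lb_scores <- function(tree) {
  stopifnot(length(tree$tip.label) >= 3)
  pd <- patristic_distances(tree)
  n <- nrow(pd)
  mean_i <- rowSums(pd) / (n - 1)
  grand <- mean(mean_i)
  if (grand <= 0)
    stop("LB scores undefined: all patristic distances are zero")
  100 * (mean_i / grand - 1)
}

#' Standard deviation of tip-to-root distances
#'
#' Unrooted trees are midpoint-rooted first; the sample standard deviation
#' (n - 1 denominator) of root-to-leaf path lengths is returned.
#' Ultrametric trees give 0.
#'
#' @param tree A `phylo` with branch lengths.
#' @return Non-negative scalar.
#' @export
tip_to_root_sd <- function(tree) {
  stopifnot(length(tree$tip.label) >= 2)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have complete branch lengths")
  if (all(tree$edge.length == 0)) return(0)
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  stats::sd(depths)
}

#' Branch-length heterogeneity indices for one locus
#'
#' @param tree The locus gene tree (`phylo`, >= 3 leaves, branch lengths).
#' @return A list with `avg_pd` (mean of the upper-triangle patristic
#'   distances), `tip_root_sd` and `lb_index` (sample standard deviation of
#'   per-taxon LB scores).
#' @export
locus_branch_indices <- function(tree) {
  pd <- patristic_distances(tree)
  lb <- lb_scores(tree)
  list(avg_pd = mean(pd[upper.tri(pd)]),
       tip_root_sd = tip_to_root_sd(tree),
       lb_index = stats::sd(lb))
}

# residue counts per taxon (gaps/ambiguity excluded); zero-count taxa
# dropped with a warning
composition_counts <- function(og) {
  ints <- og_int(og)
  counts <- matrix(0L, nrow(ints), 20,
                   dimnames = list(og$taxon, AA_STATES))
  for (j in seq_len(20)) counts[, j] <- rowSums(ints == j)
  if (anyDuplicated(og$taxon)) {
    counts <- rowsum(counts, og$taxon)
  }
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning("dropping taxa with no countable residues in locus ",
            og$locus_id, ": ", paste(rownames(counts)[empty],
                                     collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  counts
}

#' Chi-square test of compositional homogeneity
#'
#' Contingency-table test of residue counts per taxon (gaps and ambiguity
#' excluded): expected counts from row/column marginals, statistic
#' `sum((O - E)^2 / E)` over cells with `E > 0`, degrees of freedom
#' `(taxa - 1) * (observed states - 1)` (states absent from the whole locus
#' are dropped), upper-tail p-value, no continuity correction.
#'
#' @param og An [orthogroup()] with at least 2 taxa carrying residues.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
composition_chisq <- function(og) {
  counts <- composition_counts(og)
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2)
    stop("composition test needs at least 2 taxa with residues")
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  ok <- E > 0
  stat <- sum((counts[ok] - E[ok])^2 / E[ok])
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Relative composition frequency variability (RCFV)
#'
#' With `f_ij` the relative frequency of residue j in taxon i (gaps and
#' ambiguity excluded) and `mu_j` the across-taxon mean frequency,
#' `RCFV = sum_i sum_j |f_ij - mu_j| / n_taxa`.  Zero iff all taxa have
#' identical composition; higher values indicate stronger compositional
#' heterogeneity.
#'
#' @param og An [orthogroup()] with at least 2 taxa carrying residues.
#' @return Non-negative scalar.
#' @export
rcfv <- function(og) {
  counts <- composition_counts(og)
  if (nrow(counts) < 2) stop("RCFV needs at least 2 taxa with residues")
  f <- counts / rowSums(counts)
  mu <- colMeans(f)
  sum(abs(sweep(f, 2, mu))) / nrow(counts)
}

#' Flag outliers by the interquartile-range rule
#'
#' `flag_i = value_i >= median + multiplier * IQR` with linear-interpolation
#' (type-7) quantiles and `IQR = Q3 - Q1`.  When all values are equal the
#' IQR is 0 and every value is flagged; callers should skip filtering in
#' that degenerate case.
#'
#' @param values Numeric vector, length >= 4 (quartiles are unstable below
#'   that).
#' @param multiplier Positive IQR multiplier (default 1.5).
#' @return Logical vector in input order.
#' @export
iqr_flags <- function(values, multiplier = 1.5) {
  stopifnot(is.numeric(values), multiplier > 0)
  if (length(values) < 4)
    stop("iqr_flags needs at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  values >= q[2] + multiplier * (q[3] - q[1])
}

#' Per-locus diagnostics table
#'
#' Computes all branch-length and compositional heterogeneity indices for a
#' set of loci.
#'
#' @param orthogroups List of [orthogroup()] objects.
#' @param trees List of `phylo` gene trees, parallel to `orthogroups`.
#' @return A tibble of class `locus_diagnostics` with columns `locus_id`,
#'   `avg_pd`, `tip_root_sd`, `lb_index`, `rcfv`, `chisq_p`.
#' @export
locus_diagnostics <- function(orthogroups, trees) {
  stopifnot(length(orthogroups) == length(trees))
  rows <- purrr::map2(orthogroups, trees, function(og, tr) {
    bi <- locus_branch_indices(tr)
    tibble::tibble(locus_id = og$locus_id, avg_pd = bi$avg_pd,
                   tip_root_sd = bi$tip_root_sd, lb_index = bi$lb_index,
                   rcfv = rcfv(og), chisq_p = composition_chisq(og)$p_value)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("locus_diagnostics", class(out))
  out
}

#' Two-stage locus elimination
#'
#' Stage 1 removes loci flagged by the IQR rule on any branch-length index
#' (`avg_pd`, `tip_root_sd`, `lb_index`).  Stage 2, with quantiles computed
#' only on the stage-1 survivors, removes loci whose compositional
#' chi-square p-value is below `alpha` or whose RCFV is IQR-flagged.
#' Stages with a zero IQR skip the corresponding flag (degenerate,
#' all-equal indices).
#'
#' @param diagnostics A [locus_diagnostics()] tibble.
#' @param alpha Chi-square significance level (default 0.05).
#' @param multiplier IQR multiplier (default 1.5).
#' @return List with `retained` (locus ids) and `report` (tibble with an
#'   `eliminated_by` column: comma-separated causes among PD, TIPROOT, LB,
#'   CHI2, RCFV, or `""`).
#' @export
filter_loci <- function(diagnostics, alpha = 0.05, multiplier = 1.5) {
  d <- diagnostics
  n <- nrow(d)
  safe_flags <- function(x) {
    if (n < 4) return(rep(FALSE, n))
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    if (q[2] - q[1] <= 0) return(rep(FALSE, n))
    iqr_flags(x, multiplier)
  }
  causes <- rep("", n)
  add_cause <- function(causes, flag, label) {
    ifelse(flag, ifelse(causes == "", label,
                        paste(causes, label, sep = ",")), causes)
  }
  f_pd <- safe_flags(d$avg_pd)
  f_tr <- safe_flags(d$tip_root_sd)
  f_lb <- safe_flags(d$lb_index)
  causes <- add_cause(causes, f_pd, "PD")
  causes <- add_cause(causes, f_tr, "TIPROOT")
  causes <- add_cause(causes, f_lb, "LB")
  stage1 <- !(f_pd | f_tr | f_lb)
  # stage 2 quantiles computed on stage-1 survivors only
  f_chi <- stage1 & !is.na(d$chisq_p) & d$chisq_p < alpha
  f_rcfv <- rep(FALSE, n)
  if (sum(stage1) >= 4) {
    q <- stats::quantile(d$rcfv[stage1], c(0.25, 0.5, 0.75), type = 7,
                         names = FALSE)
    if (q[3] - q[1] > 0)
      f_rcfv <- stage1 & (d$rcfv >= q[2] + multiplier * (q[3] - q[1]))
  }
  causes <- add_cause(causes, f_chi, "CHI2")
  causes <- add_cause(causes, f_rcfv, "RCFV")
  retained <- stage1 & !f_chi & !f_rcfv
  list(retained = d$locus_id[retained],
       report = dplyr::mutate(tibble::as_tibble(d),
                              eliminated_by = causes,
                              retained = retained))
}

#' Distribution plot for locus diagnostics
#'
#' Histograms of each heterogeneity index with the IQR elimination cutoff.
#'
#' @param object A [locus_diagnostics()] tibble.
#' @param multiplier IQR multiplier used for the cutoff lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.locus_diagnostics <- function(object, multiplier = 1.5, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("avg_pd", "tip_root_sd", "lb_index", "rcfv"),
                              names_to = "index")
  cuts <- dplyr::summarise(
    dplyr::group_by(long, .data$index),
    cutoff = stats::quantile(.data$value, 0.5, type = 7) +
      multiplier * stats::IQR(.data$value, type = 7))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(data = cuts,
                        ggplot2::aes(xintercept = .data$cutoff),
                        linetype = 2) +
    ggplot2::facet_wrap(~index, scales = "free") +
    ggplot2::theme_minimal()
}
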