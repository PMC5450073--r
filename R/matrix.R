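MISSING_CHARS <- c("-", "X", "?")

new_supermatrix <- function(mat, partitions) {
  structure(list(taxa = rownames(mat), mat = mat, partitions = partitions),
            class = "supermatrix")
}

#' Concatenate pruned loci into a supermatrix
#'
#' Builds the one-row-per-taxon concatenated alignment over the union of
#' taxa across loci, gap-padding cells where a taxon lacks a locus, and
#' records an ordered partition table (1-based inclusive coordinates, RAxML
#' dialect).  Loci keep their input order; each locus must already be
#' reduced to at most one sequence per taxon.
#'
#' @param orthogroups List of [orthogroup()] objects, one per locus.
#' @param models Optional character vector of per-locus model names recorded
#'   in the partition table (recycled; default `"AUTO"`).
#' @return An object of class `supermatrix`: taxa, character matrix, and a
#'   `partitions` tibble with columns `locus_id`, `start`, `end`, `model`.
#' @examples
#' og1 <- orthogroup("a", c("t1", "t2"), c("t1|1", "t2|1"), c("MKL", "MKI"))
#' og2 <- orthogroup("b", c("t1", "t3"), c("t1|1", "t3|1"), c("FFQA", "FYQA"))
#' sm <- concatenate_orthogroups(list(og1, og2))
#' sm$partitions
#' @export
concatenate_orthogroups <- function(orthogroups, models = "AUTO") {
  stopifnot(length(orthogroups) > 0)
  for (og in orthogroups) {
    if (anyDuplicated(og$taxon))
      stop("locus ", og$locus_id,
           " has more than one sequence for a taxon; prune first")
  }
  taxa <- unique(unlist(lapply(orthogroups, og_taxa)))
  lens <- vapply(orthogroups, og_length, integer(1))
  ids <- vapply(orthogroups, function(o) o$locus_id, character(1))
  models <- rep_len(models, length(orthogroups))
  total <- sum(lens)
  mat <- matrix("-", length(taxa), total, dimnames = list(taxa, NULL))
  end <- cumsum(lens)
  start <- end - lens + 1L
  for (i in seq_along(orthogroups)) {
    og <- orthogroups[[i]]
    if (og_length(og) == 0) next
    mat[og$taxon, start[i]:end[i]] <- og$mat
  }
  parts <- tibble::tibble(locus_id = ids, start = as.integer(start),
                          end = as.integer(end), model = models)
  new_supermatrix(mat, parts)
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d characters, %d loci\n",
              length(x$taxa), ncol(x$mat), nrow(x$partitions)))
  invisible(x)
}

#' Remove gappy alignment columns
#'
#' Drops columns whose gap proportion is strictly greater than
#' `max_gap_fraction` (the TrimAl `>50%` rule at the default).  Ambiguity
#' codes count as residues here; only `"-"` is a gap.  Applied to a
#' supermatrix, partition coordinates are recomputed.
#'
#' @param x An [orthogroup()] or supermatrix.
#' @param max_gap_fraction Columns with gap proportion strictly above this
#'   are removed (default 0.5).
#' @return Same type as `x`.
#' @export
remove_gappy_sites <- function(x, max_gap_fraction = 0.5) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  UseMethod("remove_gappy_sites")
}

gappy_cols <- function(mat, max_gap_fraction) {
  if (nrow(mat) == 0 || ncol(mat) == 0) return(logical(ncol(mat)))
  colMeans(mat == "-") > max_gap_fraction
}

#' @export
remove_gappy_sites.orthogroup <- function(x, max_gap_fraction = 0.5) {
  drop <- gappy_cols(x$mat, max_gap_fraction)
  orthogroup(x$locus_id, x$taxon, x$seq_id, x$mat[, !drop, drop = FALSE])
}

#' @export
remove_gappy_sites.supermatrix <- function(x, max_gap_fraction = 0.5) {
  drop <- gappy_cols(x$mat, max_gap_fraction)
  keep_n <- vapply(seq_len(nrow(x$partitions)), function(i) {
    sum(!drop[x$partitions$start[i]:x$partitions$end[i]])
  }, integer(1))
  end <- cumsum(keep_n)
  parts <- tibble::tibble(locus_id = x$partitions$locus_id,
                          start = as.integer(end - keep_n + 1L),
                          end = as.integer(end),
                          model = x$partitions$model)
  new_supermatrix(x$mat[, !drop, drop = FALSE], parts)
}

#' Missing data percentages
#'
#' Per taxon, 100 x (number of `"-"`, `"X"` or `"?"` cells) / alignment
#' length; the overall value is the mean cell-level missingness (ambiguity
#' counts as missing, following TREE-PUZZLE semantics).
#'
#' @param sm A supermatrix.
#' @return A list with `per_taxon` (tibble: `taxon`, `pct_missing`) and
#'   `overall` (scalar percentage).
#' @export
percent_missing <- function(sm) {
  miss <- matrix(sm$mat %in% MISSING_CHARS, nrow = nrow(sm$mat))
  per <- 100 * rowMeans(miss)
  list(per_taxon = tibble::tibble(taxon = sm$taxa, pct_missing = unname(per)),
       overall = 100 * mean(miss))
}

#' Count parsimony-informative characters
#'
#' A column is parsimony-informative when at least two distinct unambiguous
#' residues each occur in at least two sequences; gaps and ambiguity codes
#' are ignored.
#'
#' @param sm A supermatrix (or any object with a character matrix `$mat`).
#' @return Integer count.
#' @export
count_parsimony_informative <- function(sm) {
  mat <- sm$mat
  if (ncol(mat) == 0) return(0L)
  sum(vapply(seq_len(ncol(mat)), function(j) {
    tab <- table(mat[mat[, j] %in% AA_STATES, j])
    sum(tab >= 2) >= 2
  }, logical(1)))
}

#' Summarise a supermatrix
#'
#' One-row table of the usual data-matrix characteristics: number of loci,
#' characters, parsimony-informative characters and percent missing data.
#'
#' @param sm A supermatrix.
#' @return A one-row tibble.
#' @export
summarize_supermatrix <- function(sm) {
  tibble::tibble(
    n_taxa = length(sm$taxa),
    n_loci = nrow(sm$partitions),
    n_characters = ncol(sm$mat),
    n_parsimony_informative = as.integer(count_parsimony_informative(sm)),
    pct_missing = percent_missing(sm)$overall
  )
}

#' @export
#' @importFrom generics glance
glance.supermatrix <- function(x, ...) summarize_supermatrix(x)

#' Occupancy plot for a supermatrix
#'
#' Presence/absence of each locus in each taxon, shaded by the proportion
#' of non-missing cells in that locus block.
#'
#' @param object A supermatrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @importFrom ggplot2 autoplot
autoplot.supermatrix <- function(object, ...) {
  p <- object$partitions
  cells <- purrr::map_dfr(seq_len(nrow(p)), function(i) {
    block <- object$mat[, p$start[i]:p$end[i], drop = FALSE]
    tibble::tibble(locus_id = p$locus_id[i], taxon = object$taxa,
                   coverage = rowMeans(!matrix(block %in% MISSING_CHARS,
                                               nrow = nrow(block))))
  })
  ggplot2::ggplot(cells, ggplot2::aes(
    x = factor(.data$locus_id, levels = p$locus_id),
    y = .data$taxon, fill = .data$coverage)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey20",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "locus", y = NULL, fill = "coverage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
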