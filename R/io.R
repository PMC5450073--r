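#' Read and write aligned orthogroup FASTA files
#'
#' Orthogroups are stored one FASTA file per locus; record names are
#' sequence ids encoding the taxon of origin (see [taxon_from_id()]).
#'
#' @param path FASTA file path.
#' @param locus_id Locus id; defaults to the file name without extension.
#' @param delim Taxon/copy delimiter within sequence ids.
#' @return [read_orthogroup()] returns an [orthogroup()];
#'   [write_orthogroup()] returns `path` invisibly.
#' @export
read_orthogroup <- function(path, locus_id = NULL, delim = "|") {
  if (is.null(locus_id))
    locus_id <- sub("\\.[^.]*$", "", basename(path))
  bin <- ape::read.FASTA(path, type = "AA")
  mat <- toupper(as.character(as.matrix(bin)))
  ids <- rownames(mat)
  orthogroup(locus_id, taxon_from_id(ids, delim), ids, mat)
}

#' @rdname read_orthogroup
#' @param og An [orthogroup()].
#' @export
write_orthogroup <- function(og, path) {
  seqs <- lapply(seq_len(nrow(og$mat)),
                 function(i) og$mat[i, ])
  names(seqs) <- og$seq_id
  ape::write.FASTA(ape::as.AAbin(seqs), path)
  invisible(path)
}

#' Read and write gene trees in Newick format
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()]; internal
#' node labels hold support values in `[0, 1]` when present.
#'
#' @param path Newick file path.
#' @param tree A `phylo` object.
#' @return A `phylo` object, or `path` invisibly for the writer.
#' @export
read_gene_tree <- function(path) ape::read.tree(path)

#' @rdname read_gene_tree
#' @export
write_gene_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a supermatrix and its partition table
#'
#' The alignment is written as aligned FASTA or relaxed PHYLIP; partitions
#' are written in RAxML format, one line per locus:
#' `<MODEL>, <locus_id> = <start>-<end>` (1-based inclusive coordinates).
#'
#' @param sm A [supermatrix] (see [concatenate_orthogroups()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_supermatrix_fasta <- function(sm, path) {
  seqs <- lapply(seq_len(nrow(sm$mat)), function(i) sm$mat[i, ])
  names(seqs) <- sm$taxa
  ape::write.FASTA(ape::as.AAbin(seqs), path)
  invisible(path)
}

#' @rdname write_supermatrix_fasta
#' @export
write_supermatrix_phylip <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(sm$taxa), ncol(sm$mat)), con)
  rows <- apply(sm$mat, 1, paste, collapse = "")
  writeLines(sprintf("%s  %s", sm$taxa, rows), con)
  invisible(path)
}

#' @rdname write_supermatrix_fasta
#' @export
write_partitions <- function(sm, path) {
  p <- sm$partitions
  writeLines(sprintf("%s, %s = %d-%d", p$model, p$locus_id, p$start, p$end),
             path)
  invisible(path)
}

#' Read a supermatrix back from disk
#'
#' @param alignment_path FASTA or relaxed PHYLIP alignment path.
#' @param partition_path RAxML-style partition file path.
#' @param format `"fasta"` or `"phylip"`.
#' @return A [supermatrix].
#' @export
read_supermatrix <- function(alignment_path, partition_path,
                             format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    mat <- toupper(as.character(as.matrix(
      ape::read.FASTA(alignment_path, type = "AA"))))
  } else {
    ln <- readLines(alignment_path)
    ln <- ln[nzchar(trimws(ln))][-1]
    parts <- strsplit(trimws(ln), "\\s+")
    mat <- do.call(rbind, lapply(parts, function(p)
      strsplit(toupper(p[[2]]), "")[[1]]))
    rownames(mat) <- vapply(parts, `[[`, character(1), 1L)
  }
  pl <- readLines(partition_path)
  pl <- pl[nzchar(trimws(pl))]
  m <- regmatches(pl, regexec(
    "^\\s*(\\S+)\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", pl))
  parts <- tibble::tibble(
    locus_id = vapply(m, `[[`, character(1), 3L),
    start = as.integer(vapply(m, `[[`, character(1), 4L)),
    end = as.integer(vapply(m, `[[`, character(1), 5L)),
    model = vapply(m, `[[`, character(1), 2L))
  new_supermatrix(mat, parts)
}
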