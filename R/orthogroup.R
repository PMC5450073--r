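#' Aligned orthogroup objects
#'
#' An orthogroup is one aligned amino-acid locus, possibly with several
#' sequences per taxon (pre-pruning).  Internally the alignment is a
#' character matrix with one row per sequence record; rows carry a taxon id
#' and a sequence id (unique within the locus).
#'
#' @param locus_id Single string naming the locus.
#' @param taxon Character vector of taxon ids, one per record.
#' @param seq_id Character vector of sequence ids, one per record.
#' @param sequences Aligned sequences: either a character vector of equal
#'   length strings or a character matrix (records x columns).
#' @return An object of class `orthogroup`.
#' @examples
#' og <- orthogroup("loc1", c("A", "B"), c("A|c1", "B|c1"), c("MK-L", "MKAL"))
#' og_length(og)
#' @export
orthogroup <- function(locus_id, taxon, seq_id, sequences) {
  stopifnot(is.character(locus_id), length(locus_id) == 1)
  if (is.matrix(sequences)) {
    mat <- sequences
  } else {
    stopifnot(is.character(sequences))
    n <- nchar(sequences)
    if (length(unique(n)) > 1)
      stop("all sequences in an orthogroup must have equal aligned length")
    mat <- if (length(sequences))
      do.call(rbind, strsplit(sequences, "", fixed = TRUE))
    else matrix(character(), 0, 0)
  }
  taxon <- as.character(taxon)
  seq_id <- as.character(seq_id)
  stopifnot(length(taxon) == nrow(mat), length(seq_id) == nrow(mat))
  if (anyDuplicated(seq_id))
    stop("sequence ids must be unique within an orthogroup")
  mat <- toupper(mat)
  rownames(mat) <- seq_id
  structure(list(locus_id = locus_id, taxon = taxon, seq_id = seq_id,
                 mat = mat),
            class = "orthogroup")
}

#' @export
print.orthogroup <- function(x, ...) {
  cat(sprintf("<orthogroup> %s: %d sequences, %d taxa, %d columns\n",
              x$locus_id, nrow(x$mat), length(unique(x$taxon)),
              ncol(x$mat)))
  invisible(x)
}

#' @rdname orthogroup
#' @param og,x An `orthogroup`.
#' @export
og_length <- function(og) ncol(og$mat)

#' @rdname orthogroup
#' @export
og_taxa <- function(og) unique(og$taxon)

#' @rdname orthogroup
#' @export
og_n_records <- function(og) nrow(og$mat)

# sequences as strings, named by seq_id
og_strings <- function(og) {
  stats::setNames(apply(og$mat, 1, paste, collapse = ""), og$seq_id)
}

# non-gap residue count per record ("-" and ambiguity "X"/"?" excluded)
og_residue_counts <- function(og) {
  rowSums(matrix(og$mat %in% AA_STATES, nrow = nrow(og$mat)))
}

# subset records, dropping all-gap columns optionally
og_subset <- function(og, keep, drop_gap_cols = FALSE) {
  mat <- og$mat[keep, , drop = FALSE]
  taxon <- og$taxon[keep]
  seq_id <- og$seq_id[keep]
  if (drop_gap_cols && nrow(mat) > 0) {
    all_gap <- colSums(matrix(mat %in% AA_STATES, nrow = nrow(mat))) == 0
    mat <- mat[, !all_gap, drop = FALSE]
  }
  orthogroup(og$locus_id, taxon, seq_id, mat)
}

#' @rdname orthogroup
#' @param ... Unused.
#' @export
#' @importFrom tibble as_tibble tibble
as_tibble.orthogroup <- function(x, ...) {
  tibble::tibble(locus_id = x$locus_id, taxon_id = x$taxon,
                 sequence_id = x$seq_id,
                 sequence = unname(og_strings(x)))
}

#' Extract the taxon id from a sequence id
#'
#' Sequence ids follow transcriptome contig naming, `"taxon|copyN"`: the
#' taxon is everything before the first delimiter.
#'
#' @param ids Character vector of sequence ids.
#' @param delim Delimiter (default `"|"`).
#' @return Character vector of taxon ids.
#' @export
taxon_from_id <- function(ids, delim = "|") {
  vapply(strsplit(ids, delim, fixed = TRUE), `[[`, character(1), 1L)
}

# integer-coded alignment (1..20, 0 = gap/ambiguous), rows = records
og_int <- function(og) {
  m <- match(og$mat, AA_STATES, nomatch = 0L)
  matrix(m, nrow = nrow(og$mat), dimnames = dimnames(og$mat))
}
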