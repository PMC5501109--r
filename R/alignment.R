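# CuratedAlignment: a protein multiple alignment with per-sequence paralog
# group labels, an optional per-column exon-index annotation (the family
# exon partition) and a designated reference row whose residue numbering all
# reported positions refer to.

#' Construct a curated alignment
#'
#' @param seqs Named character vector of equal-length aligned protein
#'   sequences (gaps `-`).
#' @param groups Character vector of paralog group labels, one per sequence
#'   (recycled names from `seqs` when named).
#' @param exon_index Optional integer vector (one per column) assigning each
#'   column to a family exon (1..E, non-decreasing), `NA` for columns outside
#'   modeled exons.
#' @param reference Id of the reference row used for residue numbering.
#' @return Object of class `CuratedAlignment`.
#' @export
curated_alignment <- function(seqs, groups, exon_index = NULL,
                              reference = NULL) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  w <- unique(nchar(seqs))
  if (length(w) != 1) stop("alignment rows differ in length")
  if (!is.null(names(groups))) groups <- groups[names(seqs)]
  stopifnot(length(groups) == length(seqs))
  if (!is.null(exon_index)) {
    stopifnot(length(exon_index) == w)
    ei <- exon_index[!is.na(exon_index)]
    if (length(ei) && any(diff(ei) < 0))
      stop("column exon indices must be non-decreasing")
  }
  if (!is.null(reference) && !reference %in% names(seqs))
    stop("reference row not present: ", reference)
  structure(list(seqs = seqs, groups = stats::setNames(groups, names(seqs)),
                 exon_index = exon_index, reference = reference,
                 width = w),
            class = "CuratedAlignment")
}

#' @export
print.CuratedAlignment <- function(x, ...) {
  cat(sprintf("CuratedAlignment: %d sequences x %d columns, %d group(s)%s\n",
              length(x$seqs), x$width, length(unique(x$groups)),
              if (!is.null(x$exon_index))
                sprintf(", %d exon(s)", max(x$exon_index, na.rm = TRUE))
              else ""))
  invisible(x)
}

# Character matrix view (rows = sequences, cols = columns).
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- names(aln$seqs)
  m
}

# Map an alignment column to the 1-based residue number of the reference
# row; NA when the reference is gapped at that column.
aln_reference_positions <- function(aln) {
  if (is.null(aln$reference)) return(seq_len(aln$width))
  ref <- strsplit(aln$seqs[[aln$reference]], "")[[1]]
  pos <- cumsum(ref != "-")
  pos[ref == "-"] <- NA
  pos
}
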