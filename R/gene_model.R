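# GeneModel: ordered exons with genomic coordinates plus optional CDS-bearing
# sequence. Internal coordinates are 0-based half-open on the forward strand
# throughout the package; GFF3 I/O converts to/from 1-based inclusive.

#' Construct a gene model
#'
#' A gene model is an ordered list of coding exons, each located on a contig
#' interval and strand, with an optional backing sequence (used by the
#' simulator, where coordinates are relative to the gene's own region) and a
#' record of exons missing from the assembly.
#'
#' @param id Unique gene/copy identifier.
#' @param label Paralog (orthology-group) label the copy belongs to.
#' @param exons `data.frame` with columns `contig`, `start`, `end` (0-based
#'   half-open, forward strand), `strand` (`"+"`/`"-"`) and `exon_index`
#'   (1-based index into the family exon partition). Rows are kept in
#'   `exon_index` order.
#' @param seq Optional backing nucleotide sequence when all exons live in one
#'   local coordinate frame (contig column then names that frame).
#' @param missing_exons Integer vector of family exon indices with no hit.
#' @param status One of `"intact"`, `"pseudogene"`, `"retrogene"`,
#'   `"pseudo-retrogene"`, or `NA` when not yet classified.
#' @return An object of class `GeneModel`.
#' @export
gene_model <- function(id, label, exons, seq = NULL,
                       missing_exons = integer(0), status = NA_character_) {
  stopifnot(is.data.frame(exons),
            all(c("contig", "start", "end", "strand", "exon_index") %in%
                  names(exons)))
  if (nrow(exons) > 0) {
    stopifnot(all(exons$start < exons$end), all(exons$start >= 0),
              all(exons$strand %in% c("+", "-")))
    exons <- exons[order(exons$exon_index), , drop = FALSE]
    rownames(exons) <- NULL
  }
  structure(list(id = id, label = label, exons = exons, seq = seq,
                 missing_exons = as.integer(missing_exons), status = status),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (paralog %s): %d exon(s), %d intron(s)",
              x$id, x$label, nrow(x$exons), nrow(gene_introns(x))))
  if (length(x$missing_exons))
    cat(sprintf(", missing exons: %s", paste(x$missing_exons, collapse = ",")))
  if (!is.na(x$status)) cat(sprintf(" [%s]", x$status))
  cat("\n")
  invisible(x)
}

#' Extract the coding sequence of a gene model
#'
#' Exon sequences are pulled from the backing sequence or from the supplied
#' contigs, reverse-complemented for minus-strand exons, and concatenated in
#' exon order.
#'
#' @param gene A [gene_model()].
#' @param contigs Named character vector (or `DNAStringSet`) of contig
#'   sequences; unused when the gene carries its own backing sequence.
#' @return A single nucleotide string.
#' @export
gene_cds <- function(gene, contigs = NULL) {
  ex <- gene$exons
  if (nrow(ex) == 0) return("")
  pieces <- character(nrow(ex))
  for (i in seq_len(nrow(ex))) {
    src <- if (!is.null(gene$seq)) gene$seq else {
      if (is.null(contigs)) stop("contigs required: gene has no backing sequence")
      as.character(contigs[[ex$contig[i]]])
    }
    s <- substr(src, ex$start[i] + 1L, ex$end[i])
    if (ex$strand[i] == "-") s <- revcomp(s)
    pieces[i] <- s
  }
  paste0(pieces, collapse = "")
}

#' List the introns of a gene model
#'
#' An intron is the genomic gap between two consecutive exons of the model
#' that lie on the same contig and strand. Gaps shorter than `min_intron`
#' nucleotides are treated as annotation jitter, not introns; consecutive
#' exons on different contigs contribute no intron (the spanning sequence is
#' not observed). The coding offset `cds_offset` is the 1-based count of
#' coding bases preceding the intron.
#'
#' @param gene A [gene_model()].
#' @param min_intron Minimum genomic gap (nt) to call an intron.
#' @return `data.frame` with columns `after_exon`, `cds_offset`, `length`,
#'   `contig`, `site_start` (forward-strand 0-based start of the intron).
#' @export
gene_introns <- function(gene, min_intron = 4L) {
  ex <- gene$exons
  out <- data.frame(after_exon = integer(0), cds_offset = integer(0),
                    length = integer(0), contig = character(0),
                    site_start = integer(0))
  if (nrow(ex) < 2) return(out)
  cum <- cumsum(ex$end - ex$start)
  for (i in seq_len(nrow(ex) - 1L)) {
    a <- ex[i, ]; b <- ex[i + 1L, ]
    if (a$contig != b$contig || a$strand != b$strand) next
    gap <- if (a$strand == "+") b$start - a$end else a$start - b$end
    if (gap >= min_intron) {
      out <- rbind(out, data.frame(
        after_exon = a$exon_index, cds_offset = cum[i], length = gap,
        contig = a$contig,
        site_start = if (a$strand == "+") a$end else b$end))
    }
  }
  out
}

# Total coding length of a gene model.
gene_cds_length <- function(gene) sum(gene$exons$end - gene$exons$start)
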