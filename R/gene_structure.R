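# Homologize exon-intron structures across genes: intron positions are
# expressed as reference-protein residue number plus phase letter (a/b/c =
# after the 1st/2nd/3rd base of that codon, e.g. "85c"), structures are
# diffed against a reference, protosplice context (AG|GY) is detected, and
# gene copies are classified as intact, pseudogene, retrogene or
# pseudo-retrogene.

#' Closed-form intron coordinate label
#'
#' For an intron after coding base `n` (1-based count of coding bases
#' preceding it), the own-codon index is `ceiling(n/3)` and the phase is
#' `((n-1) mod 3) + 1`, written as letters a/b/c.
#'
#' @param n Coding offset(s) of the intron(s).
#' @param residue Optional residue number(s) overriding `ceiling(n/3)`
#'   (after projection onto a reference).
#' @return Character label(s) such as `"85c"`.
#' @export
intron_label <- function(n, residue = NULL) {
  i <- if (is.null(residue)) ceiling(n / 3) else residue
  phase <- ((n - 1) %% 3) + 1
  paste0(i, c("a", "b", "c")[phase])
}

# inverse: "85c" -> coding offset 255 (relative to the reference CDS)
.label_to_offset <- function(label) {
  i <- as.integer(sub("[abc]$", "", label))
  r <- match(sub("^[0-9]+", "", label), c("a", "b", "c"))
  3L * (i - 1L) + r
}

#' Infer the introns of an assembled gene copy
#'
#' Structure-aware variant of [gene_introns()] for copies assembled from
#' exon hits, where some family exons may lack a hit: the genomic gap
#' between two observed exons is first reduced by the expected coding
#' length of the missing exons between them (an undetected exon inside a
#' contiguous coding stretch — e.g. in a retrogene — must not be miscalled
#' as an intron), and coding offsets count the missing exons' expected
#' lengths so intron coordinates stay on the family scale.
#'
#' When contig sequences are supplied, each intron additionally carries its
#' 4-base exonic junction context (two coding bases before, two after — the
#' protosplice motif scale), read from the observed exon flanks so it is
#' valid even when the intron's exact genomic span is ambiguous; and introns
#' spanning a contig boundary (the gap between consecutive exons on
#' different contigs, with no family exon missing between them) are called
#' from splice evidence — a `GT` donor after the upstream exon and an `AG`
#' acceptor before the downstream one — with unknown length
#' (`cross_contig = TRUE`).
#'
#' @param gene A [gene_model()].
#' @param expected_exon_lengths Expected coding length (nt) per family exon
#'   index (positional or named by index).
#' @param min_intron Minimum residual gap (nt) to call an intron.
#' @param contigs Optional named contig sequences for junction context and
#'   cross-contig intron calls.
#' @return As [gene_introns()], plus columns `cross_contig` and (with
#'   `contigs`) `context`.
#' @export
recovered_introns <- function(gene, expected_exon_lengths,
                              min_intron = 4L, contigs = NULL) {
  ex <- gene$exons
  exp_of <- function(e) {
    v <- if (!is.null(names(expected_exon_lengths)))
      expected_exon_lengths[as.character(e)] else expected_exon_lengths[e]
    ifelse(is.na(v), 0L, v)
  }
  # strand-aware exonic/intronic 2-base flanks of an exon row
  flank <- function(row, side, where) {
    # side: "up" = gene-5' of the exon, "down" = gene-3'
    # where: "exon" = last/first 2 coding bases, "intron" = adjacent 2
    sq <- contigs[[row$contig]]
    plus <- row$strand == "+"
    go_down <- (side == "down")
    if (plus == go_down) {   # genomic right end of interest
      pos <- if (where == "exon") c(row$end - 1L, row$end) else
        c(row$end + 1L, row$end + 2L)
    } else {
      pos <- if (where == "exon") c(row$start + 1L, row$start + 2L) else
        c(row$start - 1L, row$start)
    }
    if (pos[1] < 1L || pos[2] > nchar(sq)) return(NA_character_)
    s <- substr(sq, pos[1], pos[2])
    if (plus) s else revcomp(s)
  }
  out <- list()
  if (nrow(ex) < 2) return(.empty_introns())
  cum <- 0L
  for (i in seq_len(nrow(ex) - 1L)) {
    a <- ex[i, ]; b <- ex[i + 1L, ]
    cum <- cum + (a$end - a$start)
    miss_len <- if (b$exon_index - a$exon_index > 1L)
      sum(vapply(seq(a$exon_index + 1L, b$exon_index - 1L), exp_of,
                 numeric(1))) else 0L
    ctx <- if (!is.null(contigs))
      paste0(flank(a, "down", "exon"), flank(b, "up", "exon")) else
        NA_character_
    if (a$contig != b$contig || a$strand != b$strand) {
      if (!is.null(contigs) && miss_len == 0L) {
        donor <- flank(a, "down", "intron")
        acceptor <- flank(b, "up", "intron")
        if (identical(donor, "GT") && identical(acceptor, "AG")) {
          out[[length(out) + 1L]] <- data.frame(
            after_exon = a$exon_index, cds_offset = cum,
            length = NA_integer_, contig = NA_character_,
            site_start = NA_integer_, cross_contig = TRUE, context = ctx)
        }
      }
      cum <- cum + miss_len
      next
    }
    gap <- if (a$strand == "+") b$start - a$end else a$start - b$end
    ilen <- gap - miss_len
    if (ilen >= min_intron) {
      # convention: undetected exons sit with the upstream observed exon,
      # the intron follows them
      out[[length(out) + 1L]] <- data.frame(
        after_exon = a$exon_index, cds_offset = cum + miss_len,
        length = ilen, contig = a$contig,
        site_start = if (a$strand == "+") a$end + miss_len else
          a$start - miss_len - ilen,
        cross_contig = FALSE, context = ctx)
    }
    cum <- cum + miss_len
  }
  if (!length(out)) return(.empty_introns())
  do.call(rbind, out)
}

.empty_introns <- function() {
  data.frame(after_exon = integer(0), cds_offset = integer(0),
             length = integer(0), contig = character(0),
             site_start = integer(0), cross_contig = logical(0),
             context = character(0))
}

#' Test the protosplice motif on a 4-base junction context
#'
#' @param context 4-character exonic junction context (two coding bases
#'   before the intron, two after).
#' @return Logical (`NA` for missing context).
#' @export
is_protosplice_context <- function(context) {
  ifelse(is.na(context) | nchar(context) != 4, NA,
         substr(context, 1, 2) == "AG" & substr(context, 3, 3) == "G" &
           substr(context, 4, 4) %in% c("C", "T"))
}

#' Map a gene's intron positions into reference coordinates
#'
#' Each intron's own-codon index is projected through a pairwise alignment
#' of the gene's protein to the reference protein (skipping gap columns);
#' introns that project into a reference gap are flagged `unplaced` and the
#' label falls back to the own-residue numbering.
#'
#' @param gene A [gene_model()] (introns taken from its genomic structure).
#' @param query_aln,ref_aln Equal-length gapped strings aligning the gene's
#'   translated CDS (query) to the reference protein; `NULL` for a gene
#'   colinear with the reference (identity projection).
#' @param min_intron Passed to [gene_introns()].
#' @param introns Optional intron table overriding [gene_introns()] (e.g.
#'   from [recovered_introns()] for assembled copies with missing exons).
#' @return `data.frame` with columns `cds_offset`, `own_residue`,
#'   `reference_residue`, `phase`, `label`, `unplaced`.
#' @export
map_intron_positions <- function(gene, query_aln = NULL, ref_aln = NULL,
                                 min_intron = 4L, introns = NULL) {
  ins <- if (is.null(introns)) gene_introns(gene, min_intron = min_intron)
  else introns
  cds_len <- max(gene_cds_length(gene),
                 if (nrow(ins)) max(ins$cds_offset) + 1L else 0L)
  n <- ins$cds_offset
  if (any(n <= 0 | n >= cds_len))
    stop("intron coding offset outside (0, CDS length)")
  own <- ceiling(n / 3)
  phase <- ((n - 1) %% 3) + 1
  refres <- own
  unplaced <- rep(FALSE, length(n))
  if (!is.null(query_aln)) {
    stopifnot(!is.null(ref_aln), nchar(query_aln) == nchar(ref_aln))
    q <- strsplit(query_aln, "")[[1]]
    r <- strsplit(ref_aln, "")[[1]]
    qpos <- cumsum(q != "-")
    rpos <- cumsum(r != "-")
    for (k in seq_along(own)) {
      col <- match(own[k], qpos * (q != "-"))
      if (is.na(col)) { unplaced[k] <- TRUE; next }
      if (r[col] == "-") { unplaced[k] <- TRUE; next }
      refres[k] <- rpos[col]
    }
  }
  data.frame(cds_offset = n, own_residue = own,
             reference_residue = ifelse(unplaced, NA_integer_, refres),
             phase = c("a", "b", "c")[phase],
             label = ifelse(unplaced, NA_character_,
                            paste0(refres, c("a", "b", "c")[phase])),
             unplaced = unplaced)
}

#' Diff a gene's exon-intron structure against a reference
#'
#' Set differences of intron coordinates (in reference numbering), with
#' coordinates within `tolerance` residues (same comparison applied on the
#' nucleotide scale, `3 * tolerance` nt) merged as identical — draft
#' annotations occasionally jitter boundaries by a few nucleotides.
#' `unplaced` introns are excluded. A gained intron falling inside a
#' reference exon splits it into parts labeled e.g. `"5.1"`/`"5.2"`.
#'
#' @param mapped Output of [map_intron_positions()] for the gene.
#' @param reference_labels Character vector of the reference structure's
#'   intron labels (e.g. `c("57a","85c")`).
#' @param missing_exons Integer vector of reference exons absent from the
#'   gene (reported as `lost_exons`).
#' @param tolerance Merge tolerance in residues.
#' @return List of class `StructureDiff` with `gained_introns`,
#'   `lost_introns`, `lost_exons`, `split_exons`.
#' @export
diff_structure <- function(mapped, reference_labels,
                           missing_exons = integer(0), tolerance = 1L) {
  g <- mapped[!mapped$unplaced, , drop = FALSE]
  gn <- 3L * (g$reference_residue - 1L) + match(g$phase, c("a", "b", "c"))
  rn <- .label_to_offset(reference_labels)
  tol_nt <- 3L * tolerance
  matched_g <- logical(length(gn)); matched_r <- logical(length(rn))
  if (length(gn) && length(rn)) {
    for (i in order(gn)) {
      d <- abs(rn - gn[i])
      j <- which(!matched_r & d <= tol_nt)
      if (length(j)) { j <- j[which.min(d[j])]
        matched_g[i] <- TRUE; matched_r[j] <- TRUE }
    }
  }
  gained <- g$label[!matched_g]
  lost <- reference_labels[!matched_r]
  split_exons <- list()
  if (length(gained)) {
    # exon containing a gained intron, in the reference exon numbering
    breaks <- sort(rn)
    for (lab in gained) {
      n0 <- .label_to_offset(lab)
      e <- 1L + sum(breaks < n0)
      split_exons[[length(split_exons) + 1L]] <-
        list(exon = e, parts = paste0(e, ".", 1:2), at = lab)
    }
  }
  structure(list(gained_introns = gained, lost_introns = lost,
                 lost_exons = as.integer(missing_exons),
                 split_exons = split_exons),
            class = "StructureDiff")
}

#' @export
print.StructureDiff <- function(x, ...) {
  cat("StructureDiff:",
      if (!length(x$gained_introns) && !length(x$lost_introns) &&
            !length(x$lost_exons)) "identical to reference" else "", "\n")
  if (length(x$gained_introns))
    cat("  gained introns:", paste(x$gained_introns, collapse = ", "), "\n")
  if (length(x$lost_introns))
    cat("  lost introns:", paste(x$lost_introns, collapse = ", "), "\n")
  if (length(x$lost_exons))
    cat("  lost exons:", paste(x$lost_exons, collapse = ", "), "\n")
  invisible(x)
}

#' Detect protosplice-site context at an intron
#'
#' An intron insertion site is a protosplice site when the two exonic bases
#' immediately 5' of the intron are `AG` and the exonic bases immediately 3'
#' are `G` then `C` or `T` (motif `AG|GY` across the junction). Detection is
#' case-insensitive and strand-aware.
#'
#' @param seq Contig (or unspliced gene) sequence containing the intron.
#' @param intron_start,intron_end 0-based half-open intron interval on the
#'   forward strand.
#' @param strand `"+"` or `"-"` (gene orientation).
#' @return List with `is_protosplice` (`TRUE`/`FALSE`/`NA` when context is
#'   insufficient) and `context` (4-character exonic context, 5' to 3' in
#'   gene orientation).
#' @export
detect_protosplice <- function(seq, intron_start, intron_end, strand = "+") {
  len <- nchar(seq)
  if (strand == "-") {
    seq <- revcomp(seq)
    tmp <- intron_start
    intron_start <- len - intron_end
    intron_end <- len - tmp
  }
  seq <- toupper(seq)
  if (intron_start < 2 || intron_end > len - 2)
    return(list(is_protosplice = NA, context = NA_character_))
  up <- substr(seq, intron_start - 1L, intron_start)
  down <- substr(seq, intron_end + 1L, intron_end + 2L)
  ctx <- paste0(up, down)
  ok <- up == "AG" && substr(down, 1, 1) == "G" &&
    substr(down, 2, 2) %in% c("C", "T")
  list(is_protosplice = ok, context = ctx)
}

#' Classify a gene copy
#'
#' A copy is a retrogene when it is encoded by a single exon while the
#' family structure has two or more; a pseudogene when its coding sequence
#' carries premature stops or frameshifts; a pseudo-retrogene when both.
#' Frameshifts are assessed on the homologous span covered by exon hits
#' (observed exon length vs. the expected model length, modulo 3), so
#' assembly gaps are not miscalled; without expectations, a total CDS length
#' not divisible by 3 counts as one frameshift.
#'
#' @param gene A [gene_model()].
#' @param family_exon_count Number of exons in the family structure.
#' @param contigs Contig sequences (for CDS extraction when the gene lacks
#'   a backing sequence).
#' @param expected_exon_lengths Optional named (by exon index) or positional
#'   vector of expected coding lengths (nt) per family exon.
#' @param min_intron Passed to [gene_introns()].
#' @return List with `class` (one of `intact`, `pseudogene`, `retrogene`,
#'   `pseudo-retrogene`), `n_stops`, `n_frameshifts`.
#' @export
classify_gene_copy <- function(gene, family_exon_count, contigs = NULL,
                               expected_exon_lengths = NULL,
                               min_intron = 4L) {
  n_introns <- if (is.null(expected_exon_lengths))
    nrow(gene_introns(gene, min_intron = min_intron))
  else nrow(recovered_introns(gene, expected_exon_lengths,
                              min_intron = min_intron, contigs = contigs))
  single_exon <- n_introns == 0 &&
    length(unique(gene$exons$contig)) <= 1
  retro <- single_exon && family_exon_count >= 2
  cds <- gene_cds(gene, contigs)
  pep <- translate_dna(cds)
  n_stops <- sum(strsplit(substr(pep, 1, max(0, nchar(pep) - 1L)),
                          "")[[1]] == "*")
  n_fs <- 0L
  if (!is.null(expected_exon_lengths)) {
    obs <- gene$exons$end - gene$exons$start
    exp_len <- if (!is.null(names(expected_exon_lengths)))
      expected_exon_lengths[as.character(gene$exons$exon_index)] else
        expected_exon_lengths[gene$exons$exon_index]
    n_fs <- sum((obs - exp_len) %% 3L != 0L, na.rm = TRUE)
  } else if (nchar(cds) %% 3L != 0L) {
    n_fs <- 1L
  }
  pseudo <- n_stops > 0 || n_fs > 0
  cls <- if (retro && pseudo) "pseudo-retrogene" else if (retro) "retrogene"
  else if (pseudo) "pseudogene" else "intact"
  list(class = cls, n_stops = n_stops, n_frameshifts = n_fs)
}
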