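# Readers/writers for the standard formats the pipeline touches.
# Conventions: internal coordinates 0-based half-open forward strand;
# GFF3 emitted/consumed 1-based inclusive; protein positions 1-based.

#' Read a FASTA file
#'
#' Headers are split at the first whitespace into id and description.
#' Duplicate ids are an error.
#'
#' @param path Path to a FASTA file (nucleotide or protein).
#' @return Named character vector of sequences; descriptions (when present)
#'   are kept in the `"desc"` attribute.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e)))
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- stats::setNames(as.character(set), ids)
  attr(out, "desc") <- stats::setNames(desc, ids)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector (or `XStringSet`) of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' CDS features are grouped by their `Parent` into ordered exon lists.
#' GFF3 1-based inclusive coordinates are converted to internal 0-based
#' half-open. CDS phase is validated against cumulative coding length.
#'
#' @param path Path to a GFF3 file.
#' @return List of [gene_model()] objects.
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(cds) == 0) return(list())
  parent <- vapply(cds$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  label <- if (!is.null(cds$paralog)) as.character(cds$paralog) else
    rep(NA_character_, length(cds))
  eidx <- if (!is.null(cds$exon_index)) as.integer(cds$exon_index) else
    rep(NA_integer_, length(cds))
  models <- list()
  for (g in unique(parent)) {
    sel <- which(parent == g)
    ex <- data.frame(
      contig = as.character(GenomicRanges::seqnames(cds))[sel],
      start = GenomicRanges::start(cds)[sel] - 1L,
      end = GenomicRanges::end(cds)[sel],
      strand = as.character(GenomicRanges::strand(cds))[sel],
      exon_index = eidx[sel])
    if (anyNA(ex$exon_index)) {
      # order by strand-oriented genomic coordinate
      o <- order(ifelse(ex$strand == "+", 1, -1) * ex$start)
      ex <- ex[o, , drop = FALSE]
      ex$exon_index <- seq_len(nrow(ex))
    }
    ex <- ex[order(ex$exon_index), , drop = FALSE]
    ph <- as.integer(cds$phase)[sel][order(eidx[sel])]
    if (!anyNA(ph) && length(ph) > 1) {
      lens <- ex$end - ex$start
      expect <- c(0L, (3L - cumsum(lens) %% 3L) %% 3L)[seq_along(lens)]
      bad <- which(ph != expect)
      if (length(bad))
        stop(sprintf(
          "CDS phase inconsistent with cumulative length for %s (exon %s): phase %d, expected %d",
          g, paste(ex$exon_index[bad], collapse = ","), ph[bad[1]],
          expect[bad[1]]))
    }
    models[[g]] <- gene_model(id = g, label = label[sel][1], exons = ex)
  }
  unname(models)
}

#' Write gene models to GFF3
#'
#' Each model is emitted as one `gene` feature per contig it spans, plus one
#' `CDS` feature per exon carrying `Parent`, `exon_index` and `paralog`
#' attributes, with correct GFF3 phase. Coordinates are converted back to
#' 1-based inclusive.
#'
#' @param models List of [gene_model()] objects.
#' @param path Output path.
#' @export
write_gene_models_gff3 <- function(models, path) {
  rows <- list()
  for (m in models) {
    ex <- m$exons
    if (nrow(ex) == 0) next
    lens <- ex$end - ex$start
    phase <- c(0L, (3L - cumsum(lens) %% 3L) %% 3L)[seq_along(lens)]
    for (ct in unique(ex$contig)) {
      sel <- ex$contig == ct
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = ct, type = "gene", start = min(ex$start[sel]) + 1L,
        end = max(ex$end[sel]), strand = ex$strand[sel][1],
        ID = m$id, Parent = NA_character_, exon_index = NA_integer_,
        paralog = m$label, phase = NA_integer_)
    }
    for (i in seq_len(nrow(ex))) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = ex$contig[i], type = "CDS", start = ex$start[i] + 1L,
        end = ex$end[i], strand = ex$strand[i],
        ID = sprintf("%s.cds%d", m$id, ex$exon_index[i]), Parent = m$id,
        exon_index = ex$exon_index[i], paralog = m$label, phase = phase[i])
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  gr$exon_index <- df$exon_index
  gr$paralog <- df$paralog
  gr$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a rooted tree from a Newick file
#'
#' Unrooted or multifurcating trees are accepted but flagged via the
#' `"rooted"` and `"binary"` attributes (with a warning).
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  rooted <- ape::is.rooted(tr)
  binary <- ape::is.binary(tr)
  if (!rooted || !binary)
    warning("tree in ", path, " is ",
            paste(c(if (!rooted) "unrooted", if (!binary) "multifurcating"),
                  collapse = " and "))
  attr(tr, "rooted") <- rooted
  attr(tr, "binary") <- binary
  tr
}

#' Read a binary character matrix from TSV
#'
#' Rows are taxa (first column), columns are characters; cells must be
#' `0`, `1` or `?` (missing, stored as `NA`).
#'
#' @param path Path to a tab-separated file with a header line.
#' @return Integer matrix with taxa as rownames and `NA` for `?`.
#' @export
read_character_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  taxa <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  bad <- setdiff(unique(as.vector(cells)), c("0", "1", "?"))
  if (length(bad))
    stop("unknown cell symbol(s): ", paste(bad, collapse = ", "))
  m <- matrix(NA_integer_, nrow(cells), ncol(cells),
              dimnames = list(taxa, colnames(cells)))
  m[cells == "0"] <- 0L
  m[cells == "1"] <- 1L
  if (anyDuplicated(taxa)) stop("duplicate taxa in matrix")
  m
}

#' Check that all matrix taxa occur in a tree
#'
#' @param matrix Character matrix as from [read_character_matrix()].
#' @param tree `ape::phylo` tree.
#' @return Invisibly `TRUE`; errors naming the first missing taxon.
#' @export
validate_matrix_tree <- function(matrix, tree) {
  missing <- setdiff(rownames(matrix), tree$tip.label)
  if (length(missing))
    stop("taxon absent from tree: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the pipeline stages with their defaults.
#' @return Nested named list, one entry per stage.
#' @export
exonweaver_config <- function() {
  list(
    exon_search = list(
      pseudocount = 0.1,
      threshold_frac = 0.25,     # threshold = frac * max attainable score
      max_stop_frac = 0.2,       # windows with more stop codons discarded
      min_partial_codons = 10L,
      refine_window_nt = 12L
    ),
    paralog_solver = list(
      max_copies = 1L,
      copy_open_penalty = NA_real_,  # NA: mean of model max scores
      contig_level = FALSE,
      allow_split_exon = FALSE
    ),
    gene_structure = list(
      merge_tolerance = 1L,      # residues, for intron-coordinate identity
      min_intron = 4L
    ),
    event_parsimony = list(
      gain_cost = 1, loss_cost = 1, root_prior = 0L
    ),
    sdp = list(
      sh_z_cutoff = -6, mr_cutoff = 0.7, xdet_cutoff = 0.6,
      xdet_keep_below = TRUE,    # cutoff polarity as printed; configurable
      mca_cosine = 0.9,
      min_coverage = 0.7, max_redundancy = 0.98,
      conservation_min_coverage = 0.9
    ),
    synth_evolver = list(
      kappa = 2.0,
      intron_len_range = c(70L, 2000L),
      tandem_spacer_kb = c(5, 20),
      intergenic_len_range = c(1000L, 3000L)
    )
  )
}

#' Read a pipeline configuration file
#'
#' Flat YAML-like key-value text grouped by stage. Unknown stages or keys are
#' rejected; recognized values override the defaults of
#' [exonweaver_config()].
#'
#' @param path Path to a YAML config file.
#' @return Full configuration list with overrides applied.
#' @export
read_config <- function(path) {
  cfg <- exonweaver_config()
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  for (stage in names(user)) {
    if (!stage %in% names(cfg)) stop("unknown config stage: ", stage)
    for (key in names(user[[stage]])) {
      if (!key %in% names(cfg[[stage]]))
        stop("unknown config key: ", stage, ".", key)
      cfg[[stage]][[key]] <- user[[stage]][[key]]
    }
  }
  cfg
}
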