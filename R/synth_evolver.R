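# Gene-family evolution simulator: a multi-exon ancestral gene evolves
# along a rooted species tree under whole-genome duplication, tandem
# duplication, gene loss, pseudogenization, retrogene formation and
# protosplice-biased intron gain/loss, with K80 nucleotide substitutions.
# Leaf genomes are laid out with intergenic spacers and can be fragmented
# into contigs with intron/intergenic-biased breakpoints, producing a full
# ground truth (gene models, event log, exon-to-contig map) against which
# every downstream stage can be validated.

#' Simulation parameters
#'
#' Event rates are per-branch probabilities; substitutions accumulate as
#' `subst_rate * branch length` expected substitutions per site under K80.
#'
#' @param species_tree Rooted `ape::phylo` tree with branch lengths.
#' @param wgd_nodes Internal node numbers at which a whole-genome
#'   duplication doubles (and relabels) every extant gene.
#' @param tandem_dup_rate,loss_rate,pseudogenization_rate,retrogene_rate,intron_gain_rate,intron_loss_rate
#'   Per-branch, per-gene event probabilities in `[0, 1]`.
#' @param subst_rate Expected substitutions/site per branch-length unit.
#' @param kappa K80 transition/transversion rate ratio.
#' @param protosplice_bias Probability that an intron gain is forced into an
#'   exonic `AG|G[CT]` (protosplice) context.
#' @param intron_len_range Length range (nt) for newly drawn introns.
#' @param tandem_spacer Genomic distance range (nt) between tandem copies.
#' @param intergenic_len_range Length range (nt) of intergenic spacers.
#' @param sdp_columns Optional `data.frame(column, label, residue)` fixing
#'   the residue at a protein column for every leaf gene whose paralog label
#'   starts with `label` (planted specificity-determining positions).
#' @param planted_events Optional list of deterministic events, each a list
#'   with `node` (child node of the branch), `type` (`"tandem_dup"`,
#'   `"loss"`, `"pseudogenization"`, `"retrogene"`, `"intron_gain"`,
#'   `"intron_loss"`), optional `label` (gene to hit; first match) and
#'   optional `detail` (e.g. `"stop"`/`"frameshift"`).
#' @param seed Integer seed.
#' @return Object of class `EvolutionParams`.
#' @export
evolution_params <- function(species_tree, wgd_nodes = integer(0),
                             tandem_dup_rate = 0, loss_rate = 0,
                             pseudogenization_rate = 0, retrogene_rate = 0,
                             intron_gain_rate = 0, intron_loss_rate = 0,
                             subst_rate = 0.05, kappa = 2.0,
                             protosplice_bias = 1.0,
                             intron_len_range = c(70L, 2000L),
                             tandem_spacer = c(5000L, 20000L),
                             intergenic_len_range = c(1000L, 3000L),
                             sdp_columns = NULL, planted_events = NULL,
                             seed = 1L) {
  rates <- c(tandem_dup_rate, loss_rate, pseudogenization_rate,
             retrogene_rate, intron_gain_rate, intron_loss_rate)
  stopifnot(inherits(species_tree, "phylo"), ape::is.rooted(species_tree),
            all(species_tree$edge.length > 0),
            all(rates >= 0 & rates <= 1),
            protosplice_bias >= 0, protosplice_bias <= 1)
  structure(list(species_tree = species_tree,
                 wgd_nodes = as.integer(wgd_nodes),
                 tandem_dup_rate = tandem_dup_rate, loss_rate = loss_rate,
                 pseudogenization_rate = pseudogenization_rate,
                 retrogene_rate = retrogene_rate,
                 intron_gain_rate = intron_gain_rate,
                 intron_loss_rate = intron_loss_rate,
                 subst_rate = subst_rate, kappa = kappa,
                 protosplice_bias = protosplice_bias,
                 intron_len_range = intron_len_range,
                 tandem_spacer = tandem_spacer,
                 intergenic_len_range = intergenic_len_range,
                 sdp_columns = sdp_columns,
                 planted_events = planted_events,
                 seed = as.integer(seed)),
            class = "EvolutionParams")
}

.BASES <- c("A", "C", "G", "T")
.TRANSITION <- c(A = "G", C = "T", G = "A", T = "C")

# random DNA of length n
.rand_dna <- function(n) paste0(sample(.BASES, n, replace = TRUE),
                                collapse = "")

# random coding sequence of n_codons codons without stop codons
.rand_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  paste0(sample(codons, n_codons, replace = TRUE), collapse = "")
}

.rand_intron <- function(len_range) {
  len <- sample(len_range[1]:len_range[2], 1L)
  paste0("GT", .rand_dna(len - 4L), "AG")
}

#' Build a multi-exon ancestral gene
#'
#' Random stop-free coding sequence split into exons at codon boundaries,
#' with random GT...AG introns between them, as the root gene of a
#' simulation.
#'
#' @param n_exons Number of coding exons.
#' @param exon_codons Codons per exon (recycled).
#' @param intron_len_range Intron length range (nt).
#' @param label Paralog label of the founding gene.
#' @param seed Integer seed.
#' @return A [gene_model()] with a backing sequence.
#' @export
make_ancestral_gene <- function(n_exons = 7L, exon_codons = 30L,
                                intron_len_range = c(70L, 300L),
                                label = "fam", seed = 1L) {
  with_seed(seed, {
    ec <- rep_len(exon_codons, n_exons)
    cds <- .rand_cds(sum(ec))
    introns <- replicate(n_exons - 1L, .rand_intron(intron_len_range))
    pieces <- character(0)
    exons <- data.frame(contig = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        exon_index = integer(0))
    pos <- 0L; cdspos <- 0L
    for (i in seq_len(n_exons)) {
      elen <- 3L * ec[i]
      pieces <- c(pieces, substr(cds, cdspos + 1L, cdspos + elen))
      exons <- rbind(exons, data.frame(
        contig = "gene", start = pos, end = pos + elen, strand = "+",
        exon_index = i))
      pos <- pos + elen; cdspos <- cdspos + elen
      if (i < n_exons) {
        pieces <- c(pieces, introns[i])
        pos <- pos + nchar(introns[i])
      }
    }
    gene_model(id = "anc", label = label, exons = exons,
               seq = paste0(pieces, collapse = ""), status = "intact")
  })
}

# K80 transition probabilities for expected distance d (subs/site)
.k80_probs <- function(d, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * d) - 0.5 * exp(-2 * (alpha + beta) * d)
  p_tv <- 0.25 - 0.25 * exp(-4 * beta * d)     # each of the two transversions
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = p_tv)
}

# mutate a DNA string under K80; returns character vector of bases
.mutate_bases <- function(bases, d, kappa) {
  if (d <= 0 || !length(bases)) return(bases)
  p <- .k80_probs(d, kappa)
  u <- stats::runif(length(bases))
  out <- bases
  ts <- u >= p["same"] & u < p["same"] + p["ts"]
  tv1 <- u >= p["same"] + p["ts"] & u < p["same"] + p["ts"] + p["tv"]
  tv2 <- u >= p["same"] + p["ts"] + p["tv"]
  out[ts] <- .TRANSITION[bases[ts]]
  # transversions: the two bases of the other chemical class
  other <- list(A = c("C", "T"), G = c("C", "T"),
                C = c("A", "G"), T = c("A", "G"))
  out[tv1] <- vapply(bases[tv1], function(b) other[[b]][1], "")
  out[tv2] <- vapply(bases[tv2], function(b) other[[b]][2], "")
  out
}

# Mutate a gene's backing sequence: exon bases under stop-controlled K80
# (stop codons arising by chance are redrawn), intron bases freely with the
# terminal GT/AG dinucleotides kept fixed.
.mutate_gene <- function(gene, d, kappa, allow_stops = FALSE) {
  if (d <= 0) return(gene)
  bases <- strsplit(gene$seq, "")[[1]]
  ex <- gene$exons
  exonic <- unlist(lapply(seq_len(nrow(ex)),
                          function(i) (ex$start[i] + 1L):ex$end[i]))
  cds_old <- bases[exonic]
  cds_new <- .mutate_bases(cds_old, d, kappa)
  # splice-junction exonic dinucleotides are under splice-consensus
  # constraint: hold the 2 coding bases on each side of every intron fixed
  if (nrow(ex) > 1) {
    cum <- cumsum(ex$end - ex$start)
    for (bnd in cum[-length(cum)]) {
      keep <- intersect(seq_along(cds_old), (bnd - 1L):(bnd + 2L))
      cds_new[keep] <- cds_old[keep]
    }
  }
  if (!allow_stops) {
    gc <- Biostrings::GENETIC_CODE
    for (tries in 1:50) {
      codons <- vapply(seq_len(length(cds_new) %/% 3L), function(k)
        paste0(cds_new[(3L * k - 2L):(3L * k)], collapse = ""), "")
      stops <- which(gc[codons] == "*")
      if (!length(stops)) break
      for (k in stops) {
        idx <- (3L * k - 2L):(3L * k)
        cds_new[idx] <- if (tries < 50)
          .mutate_bases(cds_old[idx], d, kappa) else cds_old[idx]
      }
    }
  }
  bases[exonic] <- cds_new
  intronic <- setdiff(seq_along(bases), exonic)
  if (length(intronic)) {
    keep <- bases[intronic]
    mut <- .mutate_bases(keep, d, kappa)
    bases[intronic] <- mut
    # restore canonical splice dinucleotides
    for (i in seq_len(nrow(ex) - 1L)) {
      if (ex$end[i] >= ex$start[i + 1L]) next
      bases[(ex$end[i] + 1L):(ex$end[i] + 2L)] <- c("G", "T")
      bases[(ex$start[i + 1L] - 1L):ex$start[i + 1L]] <- c("A", "G")
    }
  }
  gene$seq <- paste0(bases, collapse = "")
  gene
}

#' Insert an intron into a gene
#'
#' The intron (which must begin `GT` and end `AG`) is inserted after coding
#' base `cds_position`; the affected exon splits in two, downstream exon
#' coordinates shift by the intron length, and the translation of the coding
#' sequence is unchanged.
#'
#' @param gene A [gene_model()] with a backing sequence.
#' @param cds_position Coding offset (1-based count of coding bases before
#'   the new intron), strictly inside the CDS.
#' @param intron_seq Intron sequence (`GT...AG`).
#' @return The modified [gene_model()].
#' @export
plant_intron_gain <- function(gene, cds_position, intron_seq) {
  stopifnot(!is.null(gene$seq))
  cds_len <- gene_cds_length(gene)
  if (!(cds_position > 0 && cds_position < cds_len))
    stop("cds_position must lie strictly inside the CDS")
  if (substr(intron_seq, 1, 2) != "GT" ||
        substr(intron_seq, nchar(intron_seq) - 1L, nchar(intron_seq)) != "AG")
    stop("intron must begin GT and end AG")
  ex <- gene$exons
  cum <- cumsum(ex$end - ex$start)
  k <- which(cds_position <= cum)[1]
  before <- if (k > 1) cum[k - 1L] else 0L
  if (cds_position == before || (k < nrow(ex) && cds_position == cum[k]))
    stop("position falls inside an existing intron")
  g <- ex$start[k] + (cds_position - before)   # genomic insert point
  ilen <- nchar(intron_seq)
  gene$seq <- paste0(substr(gene$seq, 1L, g), intron_seq,
                     substr(gene$seq, g + 1L, nchar(gene$seq)))
  newrows <- rbind(
    data.frame(contig = ex$contig[k], start = ex$start[k], end = g,
               strand = "+", exon_index = 0L),
    data.frame(contig = ex$contig[k], start = g + ilen,
               end = ex$end[k] + ilen, strand = "+", exon_index = 0L))
  shift <- ex$start > ex$start[k]
  ex$start[shift] <- ex$start[shift] + ilen
  ex$end[shift] <- ex$end[shift] + ilen
  ex <- rbind(ex[seq_len(k - 1L), ], newrows,
              ex[seq_len(nrow(ex)) > k, ])
  ex$exon_index <- seq_len(nrow(ex))
  gene$exons <- ex
  rownames(gene$exons) <- NULL
  gene
}

# remove the intron after exon k from a gene with a backing sequence
.splice_out_intron <- function(gene, k) {
  ex <- gene$exons
  if (k >= nrow(ex)) stop("no intron after exon ", k)
  ilen <- ex$start[k + 1L] - ex$end[k]
  gene$seq <- paste0(substr(gene$seq, 1L, ex$end[k]),
                     substr(gene$seq, ex$start[k + 1L] + 1L,
                            nchar(gene$seq)))
  ex$end[k] <- ex$end[k + 1L] - ilen
  shift <- seq_len(nrow(ex)) > k + 1L
  ex$start[shift] <- ex$start[shift] - ilen
  ex$end[shift] <- ex$end[shift] - ilen
  ex <- ex[-(k + 1L), ]
  ex$exon_index <- seq_len(nrow(ex))
  gene$exons <- ex
  rownames(gene$exons) <- NULL
  gene
}

# candidate intron-gain coding offsets: codon-aligned (phase c, the
# hotspot phase; arbitrary-phase insertion is available via
# plant_intron_gain directly), away from existing boundaries and, when
# biased, inside an AG|G[CT] protosplice context of the CDS
.gain_candidates <- function(gene, protosplice, margin = 30L) {
  cds <- gene_cds(gene)
  len <- nchar(cds)
  cand <- seq_len(len - 1L)
  cand <- cand[cand %% 3L == 0L]
  cum <- cumsum(gene$exons$end - gene$exons$start)
  for (b in cum[-length(cum)])
    cand <- cand[abs(cand - b) >= margin]
  cand <- cand[cand >= margin & cand <= len - margin]
  if (protosplice) {
    ok <- vapply(cand, function(n)
      n >= 2 && substr(cds, n - 1L, n) == "AG" &&
        substr(cds, n + 1L, n + 1L) == "G" &&
        substr(cds, n + 2L, n + 2L) %in% c("C", "T"), logical(1))
    cand <- cand[ok]
  }
  cand
}

# overwrite CDS bases at 1-based coding offsets in a backing-sequence gene
.set_cds_bases <- function(gene, offsets, newbases) {
  ex <- gene$exons
  cum <- c(0L, cumsum(ex$end - ex$start))
  bases <- strsplit(gene$seq, "")[[1]]
  for (t in seq_along(offsets)) {
    off <- offsets[t]
    k <- which(off <= cum[-1])[1]
    bases[ex$start[k] + (off - cum[k])] <- newbases[t]
  }
  gene$seq <- paste0(bases, collapse = "")
  gene
}

# engineer a protosplice context at a codon-aligned coding offset n0:
# codon before the junction becomes CAG (Gln), codon after GCT (Ala),
# giving the exonic AG|GY motif an insertion endonuclease targets
.force_protosplice <- function(gene, n0) {
  stopifnot(n0 %% 3L == 0L, n0 >= 3L, n0 + 3L <= gene_cds_length(gene))
  .set_cds_bases(gene, (n0 - 2L):(n0 + 3L), c("C", "A", "G", "G", "C", "T"))
}

# create a retrogene: intronless single-exon copy of the spliced CDS
.make_retrogene <- function(gene, new_id) {
  cds <- gene_cds(gene)
  gene_model(id = new_id, label = gene$label,
             exons = data.frame(contig = "gene", start = 0L,
                                end = nchar(cds), strand = "+",
                                exon_index = 1L),
             seq = cds,
             status = if (gene$status == "intact") "retrogene" else
               "pseudo-retrogene")
}

# pseudogenize in place: plant premature stop codon(s) or a 1-nt deletion
.pseudogenize <- function(gene, detail = "stop", n_events = 2L) {
  ex <- gene$exons
  if (identical(detail, "frameshift")) {
    pos <- ex$start[1] + (ex$end[1] - ex$start[1]) %/% 2L
    gene$seq <- paste0(substr(gene$seq, 1L, pos),
                       substr(gene$seq, pos + 2L, nchar(gene$seq)))
    ex$end[1] <- ex$end[1] - 1L
    shift <- seq_len(nrow(ex)) > 1L
    ex$start[shift] <- ex$start[shift] - 1L
    ex$end[shift] <- ex$end[shift] - 1L
    gene$exons <- ex
  } else {
    # one premature stop per targeted interior exon, at a codon boundary
    cum <- cumsum(ex$end - ex$start)
    targets <- head(seq_len(nrow(ex)), n_events)
    bases <- strsplit(gene$seq, "")[[1]]
    for (k in targets) {
      before <- if (k > 1) cum[k - 1L] else 0L
      # first full codon of exon k (codon-aligned offset within CDS)
      off <- before + (3L - before %% 3L) %% 3L + 3L
      if (off + 3L > cum[k]) next
      gpos <- ex$start[k] + (off - before)
      bases[(gpos + 1L):(gpos + 3L)] <- c("T", "A", "A")
    }
    gene$seq <- paste0(bases, collapse = "")
  }
  gene$status <- if (gene$status == "retrogene") "pseudo-retrogene" else
    "pseudogene"
  gene
}

#' Simulate a gene family on a species tree
#'
#' The ancestral gene evolves along the tree: at nodes listed in
#' `wgd_nodes` every extant gene duplicates and the two ohnolog sets receive
#' new paralog labels (`label.1`/`label.2`); per branch, stochastic events
#' fire with the configured probabilities and `planted_events` fire
#' deterministically; K80 substitutions accumulate per branch, with chance
#' stop codons redrawn so only pseudogenes carry stops. Leaf genomes are
#' laid out with random intergenic spacers and random gene orientation
#' (tandem copies a configurable distance downstream of their template).
#'
#' @param ancestral_gene A [make_ancestral_gene()] result (the root gene).
#' @param params An [evolution_params()] object.
#' @return List of class `SyntheticFamily`: `genomes` (named per-species
#'   sequence vector), `genes` (per-species list of truth [gene_model()]s in
#'   genome coordinates, with `$cds` retained), `event_log` (`data.frame`),
#'   `tree`, `params`.
#' @export
simulate_family <- function(ancestral_gene, params) {
  stopifnot(inherits(params, "EvolutionParams"))
  tree <- params$species_tree
  with_seed(params$seed, {
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    genes_at <- vector("list", n_tip + tree$Nnode)
    genes_at[[root]] <- list(ancestral_gene)
    log <- list()
    note <- function(node, type, gene, detail = "") {
      log[[length(log) + 1L]] <<- data.frame(
        node = node, species = if (node <= n_tip) tree$tip.label[node] else
          NA_character_, type = type, gene = gene, detail = as.character(detail))
    }
    copy_counter <- new.env(parent = emptyenv())
    next_id <- function(base) {
      k <- (if (is.null(copy_counter[[base]])) 0L else copy_counter[[base]]) + 1L
      copy_counter[[base]] <- k
      paste0(base, "_", k)
    }

    wgd_duplicate <- function(genes, node) {
      dup <- list()
      for (g in genes) {
        g1 <- g; g2 <- g
        g1$label <- paste0(g$label, ".1"); g1$id <- next_id(g1$label)
        g2$label <- paste0(g$label, ".2"); g2$id <- next_id(g2$label)
        dup <- c(dup, list(g1, g2))
        note(node, "wgd_duplication", g$id, paste(g1$id, g2$id, sep = "|"))
      }
      dup
    }
    if (root %in% params$wgd_nodes)
      genes_at[[root]] <- wgd_duplicate(genes_at[[root]], root)

    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1]; child <- edges[e, 2]
      genes <- lapply(genes_at[[parent]], identity)
      # whole-genome duplication at the child node
      if (child %in% params$wgd_nodes && child != root)
        genes <- wgd_duplicate(genes, child)
      # planted deterministic events on this branch
      planted <- Filter(function(ev) ev$node == child,
                        params$planted_events %||% list())
      fire <- function(type, g) {
        switch(type,
          loss = NULL,
          tandem_dup = {
            d <- g; d$id <- next_id(paste0(g$label, ".t"))
            d$tandem_of <- g$id
            list(g, d)
          },
          retrogene = {
            r <- .make_retrogene(g, next_id(paste0(g$label, ".r")))
            list(g, r)
          },
          pseudogenization = list(.pseudogenize(g)),
          intron_gain = {
            use_ps <- stats::runif(1) < params$protosplice_bias
            cand <- .gain_candidates(g, use_ps)
            if (!length(cand)) cand <- .gain_candidates(g, FALSE)
            if (!length(cand)) return(list(g))
            n0 <- cand[sample.int(length(cand), 1L)]
            list(plant_intron_gain(g, n0,
                                   .rand_intron(params$intron_len_range)))
          },
          intron_loss = {
            ni <- nrow(g$exons) - 1L
            if (ni < 1L) return(list(g))
            list(.splice_out_intron(g, sample.int(ni, 1L)))
          })
      }
      out <- list()
      for (g in genes) {
        gl <- list(g)
        for (ev in planted) {
          if (!is.null(ev$label) && gl[[1]]$label != ev$label) next
          planted <- Filter(function(x) !identical(x, ev), planted)
          if (ev$type == "pseudogenization") {
            gl[[1]] <- .pseudogenize(gl[[1]], ev$detail %||% "stop")
            note(child, ev$type, gl[[1]]$id, ev$detail %||% "stop")
          } else if (ev$type == "loss") {
            note(child, "loss", gl[[1]]$id)
            gl <- list()
            break
          } else if (ev$type == "intron_gain") {
            g1 <- gl[[1]]
            use_ps <- (params$protosplice_bias > 0)
            cand <- if (use_ps) .gain_candidates(g1, TRUE) else integer(0)
            if (length(cand)) {
              n0 <- cand[sample.int(length(cand), 1L)]
            } else {
              # no surviving protosplice context: engineer one at a
              # codon-aligned interior site (or insert unbiased)
              cand3 <- .gain_candidates(g1, FALSE)
              cand3 <- cand3[cand3 %% 3L == 0L]
              if (!length(cand3)) cand3 <- .gain_candidates(g1, FALSE)
              n0 <- cand3[sample.int(length(cand3), 1L)]
              if (use_ps && n0 %% 3L == 0L)
                g1 <- .force_protosplice(g1, n0)
            }
            gl[[1]] <- plant_intron_gain(
              g1, n0, .rand_intron(params$intron_len_range))
            note(child, "intron_gain", gl[[1]]$id, n0)
          } else {
            res <- fire(ev$type, gl[[1]])
            note(child, ev$type, gl[[1]]$id,
                 if (length(res) > 1) res[[2]]$id else "")
            gl <- res
          }
        }
        if (!length(gl)) next
        # stochastic events, one draw per type per gene
        g0 <- gl[[1]]
        if (stats::runif(1) < params$loss_rate) {
          note(child, "loss", g0$id); gl <- gl[-1]
        } else {
          if (stats::runif(1) < params$tandem_dup_rate) {
            res <- fire("tandem_dup", g0)
            note(child, "tandem_dup", g0$id, res[[2]]$id)
            gl <- c(res, gl[-1])
          }
          if (stats::runif(1) < params$retrogene_rate) {
            r <- .make_retrogene(gl[[1]],
                                 next_id(paste0(gl[[1]]$label, ".r")))
            note(child, "retrogene", gl[[1]]$id, r$id)
            gl <- c(gl, list(r))
          }
          if (gl[[1]]$status == "intact" &&
                stats::runif(1) < params$pseudogenization_rate) {
            gl[[1]] <- .pseudogenize(gl[[1]])
            note(child, "pseudogenization", gl[[1]]$id, "stop")
          }
          if (stats::runif(1) < params$intron_gain_rate) {
            res <- fire("intron_gain", gl[[1]])
            if (nrow(res[[1]]$exons) > nrow(gl[[1]]$exons))
              note(child, "intron_gain", gl[[1]]$id, "")
            gl[[1]] <- res[[1]]
          }
          if (nrow(gl[[1]]$exons) > 1L &&
                stats::runif(1) < params$intron_loss_rate) {
            gl[[1]] <- .splice_out_intron(
              gl[[1]], sample.int(nrow(gl[[1]]$exons) - 1L, 1L))
            note(child, "intron_loss", gl[[1]]$id, "")
          }
        }
        out <- c(out, gl)
      }
      # substitutions along the branch
      d <- params$subst_rate * elen[e]
      out <- lapply(out, function(g)
        .mutate_gene(g, d, params$kappa,
                     allow_stops = g$status == "pseudogene"))
      genes_at[[child]] <- out
      if (!length(out) && child <= n_tip)
        warning("no surviving genes in species ", tree$tip.label[child])
    }

    # leaf emission: plant SDP residues, lay out genomes
    genomes <- character(0)
    truth <- list()
    for (i in seq_len(n_tip)) {
      sp <- tree$tip.label[i]
      genes <- genes_at[[i]]
      if (!is.null(params$sdp_columns)) {
        genes <- lapply(genes, .plant_sdp_residues,
                        spec = params$sdp_columns)
      }
      layout <- .layout_genome(genes, sp, params)
      genomes[sp] <- layout$genome
      truth[[sp]] <- layout$genes
    }
    event_log <- if (length(log)) do.call(rbind, log) else
      data.frame(node = integer(0), species = character(0),
                 type = character(0), gene = character(0),
                 detail = character(0))
    structure(list(genomes = genomes, genes = truth, event_log = event_log,
                   tree = tree, params = params),
              class = "SyntheticFamily")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fix planted SDP codons at leaf emission
.plant_sdp_residues <- function(gene, spec) {
  if (gene$status != "intact") return(gene)
  for (r in seq_len(nrow(spec))) {
    if (!startsWith(gene$label, spec$label[r])) next
    col <- spec$column[r]
    n <- 3L * (col - 1L)
    if (n + 3L > gene_cds_length(gene)) next
    gc <- Biostrings::GENETIC_CODE
    codon <- names(gc)[gc == spec$residue[r]][1]
    # locate genomic positions of the codon and overwrite
    ex <- gene$exons
    cum <- c(0L, cumsum(ex$end - ex$start))
    bases <- strsplit(gene$seq, "")[[1]]
    for (b in 1:3) {
      off <- n + b
      k <- which(off <= cum[-1])[1]
      gpos <- ex$start[k] + (off - cum[k])
      bases[gpos] <- substr(codon, b, b)
    }
    gene$seq <- paste0(bases, collapse = "")
  }
  gene
}

# lay out a species genome: intergenic spacers, random orientation, tandem
# copies placed a tandem_spacer distance downstream of their template
.layout_genome <- function(genes, species, params) {
  # order: each tandem copy directly after its template
  ids <- vapply(genes, `[[`, "", "id")
  ordered <- list()
  placed <- character(0)
  for (g in genes) {
    if (!is.null(g$tandem_of) && g$tandem_of %in% ids) next
    ordered <- c(ordered, list(g)); placed <- c(placed, g$id)
    for (t in genes)
      if (!is.null(t$tandem_of) && t$tandem_of == g$id) {
        ordered <- c(ordered, list(t)); placed <- c(placed, t$id)
      }
  }
  for (g in genes) if (!g$id %in% placed) ordered <- c(ordered, list(g))

  pieces <- character(0)
  pos <- 0L
  out <- list()
  for (g in ordered) {
    spacer_len <- if (!is.null(g$tandem_of))
      sample(params$tandem_spacer[1]:params$tandem_spacer[2], 1L) else
        sample(params$intergenic_len_range[1]:params$intergenic_len_range[2],
               1L)
    pieces <- c(pieces, .rand_dna(spacer_len))
    pos <- pos + spacer_len
    strand <- sample(c("+", "-"), 1L)
    L <- nchar(g$seq)
    gseq <- if (strand == "+") g$seq else revcomp(g$seq)
    pieces <- c(pieces, gseq)
    ex <- g$exons
    abs_ex <- if (strand == "+")
      data.frame(contig = species, start = pos + ex$start,
                 end = pos + ex$end, strand = "+",
                 exon_index = ex$exon_index)
    else
      data.frame(contig = species, start = pos + L - ex$end,
                 end = pos + L - ex$start, strand = "-",
                 exon_index = ex$exon_index)
    gm <- gene_model(id = paste0(species, ".", g$id), label = g$label,
                     exons = abs_ex, status = g$status)
    gm$cds <- gene_cds(g)
    gm$source_id <- g$id
    out <- c(out, list(gm))
    pos <- pos + L
  }
  pieces <- c(pieces, .rand_dna(
    sample(params$intergenic_len_range[1]:params$intergenic_len_range[2], 1L)))
  list(genome = paste0(pieces, collapse = ""), genes = out)
}

#' Fragment a genome into contigs
#'
#' Breakpoints partition the genome without gaps or overlap. With
#' probability `breakpoint_bias_intron` each breakpoint is drawn from
#' intronic/intergenic positions (never splitting an exon), otherwise
#' uniformly.
#'
#' @param genome Genome sequence (single string).
#' @param target_n_contigs Number of contigs to produce.
#' @param breakpoint_bias_intron Probability in `[0, 1]` of placing each
#'   breakpoint outside exons.
#' @param genes Truth gene models in genome coordinates (required for any
#'   bias > 0).
#' @param prefix Contig name prefix.
#' @param seed Integer seed.
#' @return List with `contigs` (named character vector), `breakpoints`, and
#'   `exon_map` (`data.frame`: `gene`, `exon_index`, `contig`, `start`,
#'   `end`, `strand`, `split`).
#' @export
fragment_assembly <- function(genome, target_n_contigs,
                              breakpoint_bias_intron = 1.0, genes = list(),
                              prefix = "ctg", seed = NULL) {
  len <- nchar(genome)
  if (target_n_contigs < 1L) stop("target_n_contigs must be >= 1")
  if (target_n_contigs > len) stop("more contigs requested than bases")
  with_seed(seed, {
    exonic <- logical(len - 1L)   # breakpoint p (1..len-1) splits an exon?
    for (g in genes) for (i in seq_len(nrow(g$exons))) {
      s <- g$exons$start[i]; e <- g$exons$end[i]
      if (e - s >= 2) {
        lo <- max(1L, s + 1L); hi <- min(len - 1L, e - 1L)
        if (lo <= hi) exonic[lo:hi] <- TRUE
      }
    }
    bps <- integer(0)
    avail_safe <- which(!exonic)
    avail_all <- seq_len(len - 1L)
    while (length(bps) < target_n_contigs - 1L) {
      biased <- stats::runif(1) < breakpoint_bias_intron
      pool <- setdiff(if (biased) avail_safe else avail_all, bps)
      if (!length(pool)) break
      bps <- c(bps, pool[sample.int(length(pool), 1L)])
    }
    bps <- sort(bps)
    bounds <- c(0L, bps, len)
    contigs <- character(0)
    for (i in seq_len(length(bounds) - 1L)) {
      contigs[paste0(prefix, "_", i)] <-
        substr(genome, bounds[i] + 1L, bounds[i + 1L])
    }
    cnames <- names(contigs)
    map <- list()
    for (g in genes) for (i in seq_len(nrow(g$exons))) {
      s <- g$exons$start[i]; e <- g$exons$end[i]
      ov <- which(bounds[-length(bounds)] < e & bounds[-1] > s)
      for (ci in ov) {
        map[[length(map) + 1L]] <- data.frame(
          gene = g$id, exon_index = g$exons$exon_index[i],
          contig = cnames[ci],
          start = max(s, bounds[ci]) - bounds[ci],
          end = min(e, bounds[ci + 1L]) - bounds[ci],
          strand = g$exons$strand[i], split = length(ov) > 1L)
      }
    }
    exon_map <- if (length(map)) do.call(rbind, map) else
      data.frame(gene = character(0), exon_index = integer(0),
                 contig = character(0), start = integer(0), end = integer(0),
                 strand = character(0), split = logical(0))
    list(contigs = contigs, breakpoints = bps, exon_map = exon_map)
  })
}

#' Re-express truth gene models in contig coordinates
#'
#' @param genes Truth gene models in genome coordinates.
#' @param fragmentation Result of [fragment_assembly()] for that genome.
#' @return List of [gene_model()]s whose exons reference contigs; exons
#'   split across contigs are kept as separate rows with the same index.
#' @export
truth_on_contigs <- function(genes, fragmentation) {
  em <- fragmentation$exon_map
  lapply(genes, function(g) {
    rows <- em[em$gene == g$id, , drop = FALSE]
    gm <- gene_model(id = g$id, label = g$label,
                     exons = rows[, c("contig", "start", "end", "strand",
                                      "exon_index")],
                     status = g$status)
    gm$cds <- g$cds
    gm
  })
}

#' Build a curated alignment from simulation truth
#'
#' Intact (and optionally retrogene) copies across all species are stacked
#' into an ungapped protein alignment (the simulator introduces no coding
#' indels), grouped by paralog label. The per-column exon partition is the
#' union of all intron coding offsets observed in the included copies, so a
#' copy lacking an intron at some partition boundary simply produces two
#' adjacent exon segments.
#'
#' @param sim A `SyntheticFamily` from [simulate_family()].
#' @param include_retrogenes Include retrogene rows (identical protein).
#' @param reference Row id to designate as reference (default first row).
#' @return A [curated_alignment()].
#' @export
truth_to_alignment <- function(sim, include_retrogenes = FALSE,
                               reference = NULL) {
  rows <- list()
  breaks <- integer(0)
  for (sp in names(sim$genes)) for (g in sim$genes[[sp]]) {
    if (!(g$status == "intact" ||
            (include_retrogenes && g$status == "retrogene"))) next
    ins <- gene_introns(g)
    rows[[g$id]] <- list(pep = translate_dna(g$cds), label = g$label)
    breaks <- union(breaks, ins$cds_offset)
  }
  if (!length(rows)) stop("no intact multi-exon copies in simulation")
  peps <- vapply(rows, `[[`, "", "pep")
  if (length(unique(nchar(peps))) != 1)
    stop("coding lengths differ; cannot stack ungapped alignment")
  labels <- vapply(rows, `[[`, "", "label")
  breaks <- sort(breaks)
  ncol <- nchar(peps[[1]])
  exon_index <- vapply(seq_len(ncol), function(j)
    1L + sum(breaks <= 3L * (j - 1L)), integer(1))
  curated_alignment(peps, labels, exon_index = exon_index,
                    reference = reference %||% names(peps)[1])
}
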