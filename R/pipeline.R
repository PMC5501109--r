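# End-to-end convenience layer: curated alignment -> exon models -> contig
# scan -> exact copy assignment -> gene models + classification, plus a
# reference scenario on a small simulated clade that exercises every event
# type the simulator produces.

#' Annotate an assembly with exon models from a curated alignment
#'
#' Runs the two-step procedure: builds exon- and paralog-specific models,
#' scans the contigs in all six frames, solves the copy assignment exactly,
#' and converts the solution into gene models with per-copy classification.
#'
#' @param contigs Named character vector of contigs.
#' @param aln A [curated_alignment()] with exon annotation.
#' @param max_copies Maximum copies per paralog (K).
#' @param penalty Copy-open penalty in bits; default is the mean maximal
#'   model score (discourages spurious copies).
#' @param threshold Absolute hit threshold in bits (`NULL`: per-model
#'   default).
#' @param min_partial_codons Passed to [scan_contigs()].
#' @return List with `models`, `hits`, `solution`, `genes` (list of
#'   [gene_model()]), `classifications` (`data.frame`).
#' @export
annotate_assembly <- function(contigs, aln, max_copies = 1L, penalty = NULL,
                              threshold = NULL, min_partial_codons = 10L) {
  models <- build_exon_models(aln)
  labels <- unique(vapply(models, `[[`, "", "paralog"))
  n_exons <- max(vapply(models, `[[`, 0, "exon"))
  paralogs <- data.frame(label = labels, n_exons = n_exons)
  if (is.null(penalty))
    penalty <- mean(vapply(models, `[[`, 0, "max_score"))
  hits <- scan_contigs(contigs, models,
                       threshold = threshold,
                       min_partial_codons = min_partial_codons)
  problem <- assignment_problem(hits, paralogs, max_copies = max_copies,
                                penalty = penalty)
  solution <- solve_assignment(problem)
  genes <- solution_to_gene_models(solution)
  # expected coding length per (paralog, exon) for frameshift assessment
  exp_len <- list()
  for (m in models)
    exp_len[[m$paralog]][as.character(m$exon)] <- 3L * m$length
  cls <- do.call(rbind, lapply(genes, function(g) {
    cl <- classify_gene_copy(g, family_exon_count = n_exons,
                             contigs = contigs,
                             expected_exon_lengths =
                               unlist(exp_len[[g$label]]))
    data.frame(gene = g$id, paralog = g$label,
               n_exons_found = nrow(g$exons),
               n_exons_missing = length(g$missing_exons),
               class = cl$class, n_stops = cl$n_stops,
               n_frameshifts = cl$n_frameshifts)
  }))
  for (i in seq_along(genes))
    genes[[i]]$status <- cls$class[i]
  list(models = models, hits = hits, solution = solution, genes = genes,
       classifications = cls)
}

#' Reference simulation scenario on an eight-species clade
#'
#' Builds the package's standard validation scenario: a balanced
#' eight-species tree (unit branches, depth three); one whole-genome
#' duplication at the ancestor of species s1-s4 (paralogs `fam.1`/`fam.2`);
#' one tandem duplication followed by pseudogenization of the template on
#' the branch to s7; one retrogene insertion on the branch to s8; one gene
#' loss on the branch to s6; one protosplice-biased intron gain in `fam.1`
#' in the ancestor of s1/s2. Substitutions accumulate at 0.1
#' substitutions/site per unit branch (root-to-tip expectation 0.3); each
#' genome is fragmented into contigs with breakpoints restricted to
#' intronic/intergenic sequence.
#'
#' @param seed Integer seed driving the whole scenario.
#' @param n_contigs Contigs per species genome.
#' @return List with `sim` (the `SyntheticFamily`), `assemblies` (per
#'   species: [fragment_assembly()] output), `truth` (per species: gene
#'   models in contig coordinates), `aln` (curated alignment from truth),
#'   `reference_introns` (ancestral intron labels), `gain` (planted intron
#'   gain: species, gene, cds offset, label).
#' @export
demo_scenario <- function(seed = 1L, n_contigs = 6L) {
  tree <- ape::read.tree(
    text = "(((s1:1,s2:1):1,(s3:1,s4:1):1):1,((s5:1,s6:1):1,(s7:1,s8:1):1):1);")
  wgd <- ape::getMRCA(tree, c("s1", "s4"))
  gain_node <- ape::getMRCA(tree, c("s1", "s2"))
  tip <- function(s) which(tree$tip.label == s)
  planted <- list(
    list(node = gain_node, type = "intron_gain", label = "fam.1"),
    list(node = tip("s7"), type = "tandem_dup", label = "fam"),
    list(node = tip("s7"), type = "pseudogenization", label = "fam",
         detail = "stop"),
    list(node = tip("s8"), type = "retrogene", label = "fam"),
    list(node = tip("s6"), type = "loss", label = "fam"))
  anc <- make_ancestral_gene(n_exons = 7L, exon_codons = 30L, seed = seed)
  params <- evolution_params(tree, wgd_nodes = wgd, subst_rate = 0.1,
                             planted_events = planted, seed = seed)
  sim <- suppressWarnings(simulate_family(anc, params))

  assemblies <- list(); truth <- list()
  for (i in seq_along(sim$genomes)) {
    sp <- names(sim$genomes)[i]
    frag <- fragment_assembly(sim$genomes[[sp]], n_contigs,
                              breakpoint_bias_intron = 1.0,
                              genes = sim$genes[[sp]],
                              prefix = sp, seed = seed + i)
    assemblies[[sp]] <- frag
    truth[[sp]] <- truth_on_contigs(sim$genes[[sp]], frag)
  }
  aln <- truth_to_alignment(sim)
  ref_labels <- intron_label(gene_introns(anc)$cds_offset)
  ev <- sim$event_log
  gi <- ev[ev$type == "intron_gain", , drop = FALSE]
  gain <- if (nrow(gi)) {
    n0 <- as.integer(gi$detail[1])
    list(gene = gi$gene[1], cds_offset = n0, label = intron_label(n0))
  } else NULL
  list(sim = sim, assemblies = assemblies, truth = truth, aln = aln,
       reference_introns = ref_labels, gain = gain, tree = tree)
}

#' Genomic sub-intervals of truth exons under the family exon partition
#'
#' Splits each truth exon at the family partition breaks (union of intron
#' coding offsets used by [truth_to_alignment()]), yielding the intervals
#' the scanner's exon segments should hit exactly.
#'
#' @param gene A truth [gene_model()] in contig coordinates.
#' @param breaks Sorted coding offsets of the family partition.
#' @return `data.frame` with `contig`, `start`, `end`, `strand`, `segment`
#'   (index in the family partition).
#' @export
truth_exon_segments <- function(gene, breaks) {
  ex <- gene$exons
  cum <- c(0L, cumsum(ex$end - ex$start))
  segs <- list()
  all_bounds <- sort(unique(c(0L, breaks, cum[length(cum)])))
  for (i in seq_len(nrow(ex))) {
    lo <- cum[i]; hi <- cum[i + 1L]
    inner <- all_bounds[all_bounds > lo & all_bounds < hi]
    b <- c(lo, inner, hi)
    for (k in seq_len(length(b) - 1L)) {
      seg_idx <- 1L + sum(breaks <= b[k])
      if (ex$strand[i] == "+") {
        s <- ex$start[i] + (b[k] - lo); e <- ex$start[i] + (b[k + 1L] - lo)
      } else {
        s <- ex$end[i] - (b[k + 1L] - lo); e <- ex$end[i] - (b[k] - lo)
      }
      segs[[length(segs) + 1L]] <- data.frame(
        contig = ex$contig[i], start = s, end = e, strand = ex$strand[i],
        segment = seg_idx)
    }
  }
  do.call(rbind, segs)
}

#' Evaluate pipeline recovery on the reference scenario
#'
#' Runs [annotate_assembly()] per species (K = 2) on the
#' [demo_scenario()] assemblies and measures recovery against the
#' planted truth: exact exon-segment interval recovery, per-(species,
#' paralog) copy-count agreement for copies with at least three detectable
#' segments, retrogene/pseudogene classification, and the gained intron's
#' coordinate label and protosplice context.
#'
#' @param scenario Result of [demo_scenario()].
#' @return List of recovery metrics (fractions and logicals).
#' @export
evaluate_demo_recovery <- function(scenario) {
  aln <- scenario$aln
  breaks <- sort(unique(unlist(lapply(names(scenario$sim$genes), function(sp)
    lapply(scenario$sim$genes[[sp]], function(g)
      if (g$status == "intact" && nrow(g$exons) > 1)
        gene_introns(g)$cds_offset else integer(0))))))
  n_seg_total <- 0L; n_seg_hit <- 0L
  copy_ok <- TRUE; n_copy_checked <- 0L
  classes <- list()
  gain_label <- NA_character_; gain_protosplice <- NA
  for (sp in names(scenario$assemblies)) {
    contigs <- scenario$assemblies[[sp]]$contigs
    res <- annotate_assembly(contigs, aln, max_copies = 2L)
    # exon-segment interval recovery (scanner level)
    for (g in scenario$truth[[sp]]) {
      segs <- truth_exon_segments(g, breaks)
      segs <- segs[segs$end - segs$start >= 9L, , drop = FALSE]
      n_seg_total <- n_seg_total + nrow(segs)
      for (k in seq_len(nrow(segs)))
        if (any(res$hits$contig == segs$contig[k] &
                  res$hits$start == segs$start[k] &
                  res$hits$end == segs$end[k] &
                  res$hits$strand == segs$strand[k]))
          n_seg_hit <- n_seg_hit + 1L
    }
    # copy counts per paralog label, copies with >= 3 detectable segments
    truth_counts <- table(unlist(lapply(scenario$truth[[sp]], function(g) {
      segs <- truth_exon_segments(g, breaks)
      if (nrow(segs) >= 3) g$label else NULL
    })))
    got_counts <- table(vapply(res$genes, `[[`, "", "label"))
    for (lb in union(names(truth_counts), names(got_counts))) {
      n_copy_checked <- n_copy_checked + 1L
      tc <- if (lb %in% names(truth_counts)) truth_counts[[lb]] else 0L
      gc <- if (lb %in% names(got_counts)) got_counts[[lb]] else 0L
      if (tc != gc) copy_ok <- FALSE
    }
    # classification of recovered copies, matched to truth by location
    for (g in res$genes) {
      tr <- .match_truth_copy(g, scenario$truth[[sp]])
      if (!is.null(tr))
        classes[[tr$id]] <- list(truth = tr$status, got = g$status)
    }
    # the planted intron gain: inspect the recovered fam.1 copies here
    if (!is.null(scenario$gain)) {
      planted_sp <- vapply(scenario$truth[[sp]], function(t)
        endsWith(scenario$gain$gene, t$source_id %||% "") ||
          t$id == paste0(sp, ".", scenario$gain$gene), logical(1))
      if (any(planted_sp) && is.na(gain_label)) {
        tr <- scenario$truth[[sp]][planted_sp][[1]]
        exp_len <- numeric(0)
        for (m in res$models) if (m$paralog == "fam.1")
          exp_len[as.character(m$exon)] <- 3L * m$length
        for (g in res$genes) {
          if (is.null(.match_truth_copy(g, list(tr)))) next
          ins <- recovered_introns(g, exp_len, contigs = contigs)
          mapped <- map_intron_positions(g, introns = ins)
          d <- diff_structure(mapped, scenario$reference_introns)
          if (length(d$gained_introns) == 1) {
            gain_label <- d$gained_introns[1]
            new_i <- which(mapped$label == gain_label)
            gain_protosplice <- is_protosplice_context(ins$context[new_i])
          }
        }
      }
    }
  }
  truth_cls <- vapply(classes, function(x) x$truth, "")
  got_cls <- vapply(classes, function(x) x$got, "")
  list(
    segment_recovery = n_seg_hit / n_seg_total,
    copy_counts_exact = copy_ok && n_copy_checked > 0,
    retrogene_recovered = any(truth_cls == "retrogene" &
                                got_cls == "retrogene"),
    pseudogene_recovered = any(truth_cls == "pseudogene" &
                                 got_cls == "pseudogene"),
    classification_agreement = mean(truth_cls == got_cls),
    gain_label = gain_label,
    gain_label_expected = if (!is.null(scenario$gain))
      scenario$gain$label else NA_character_,
    gain_protosplice = gain_protosplice)
}

# match a recovered gene model to the truth copy sharing most exon bases
.match_truth_copy <- function(gene, truth_genes) {
  best <- NULL; best_ov <- 0L
  for (t in truth_genes) {
    ov <- 0L
    for (i in seq_len(nrow(gene$exons))) for (j in seq_len(nrow(t$exons))) {
      if (gene$exons$contig[i] != t$exons$contig[j]) next
      ov <- ov + max(0L, min(gene$exons$end[i], t$exons$end[j]) -
                       max(gene$exons$start[i], t$exons$start[j]))
    }
    if (ov > best_ov) { best_ov <- ov; best <- t }
  }
  best
}
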