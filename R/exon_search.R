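# Step (1) of the two-step annotation procedure: build exon- and
# paralog-specific scoring models from a curated alignment and scan all six
# reading frames of assembly contigs for exon hits. Models are ungapped
# position-specific scoring matrices (log-odds, bits) — family exons are
# near-fixed-length, so ungapped scanning captures the search step without a
# full profile-HMM machinery (kept as an extension point).

#' Build exon- and paralog-specific scoring models
#'
#' For every (paralog group, exon index) pair, per-column log-odds scores
#' are computed as `log2(((count + beta * bg) / (n + beta)) / bg)` over the
#' 20 amino acids, where `n` is the number of non-gap residues in the
#' column. Columns in which gaps form the majority within the group are
#' dropped. The default hit threshold of each model is
#' `threshold_frac * maximal attainable score`.
#'
#' @param aln A [curated_alignment()] with `exon_index` column annotation.
#' @param background Amino-acid background frequencies (named, sums to 1);
#'   default BLOSUM62 marginals.
#' @param beta Pseudocount weight.
#' @param threshold_frac Fraction of the maximal model score used as the
#'   default `min_score`.
#' @return List of `ExonModel` objects (fields `paralog`, `exon`, `pssm`
#'   20 x L, `length`, `max_score`, `min_score`, `consensus`).
#' @export
build_exon_models <- function(aln, background = BLOSUM62_BACKGROUND,
                              beta = 0.1, threshold_frac = 0.25) {
  stopifnot(inherits(aln, "CuratedAlignment"))
  if (is.null(aln$exon_index))
    stop("alignment lacks per-column exon indices")
  bg <- background[AA20] / sum(background[AA20])
  m <- aln_matrix(aln)
  models <- list()
  for (p in unique(aln$groups)) {
    rows <- which(aln$groups == p)
    if (length(rows) < 2)
      stop("paralog group needs >= 2 rows: ", p)
    for (e in sort(unique(aln$exon_index[!is.na(aln$exon_index)]))) {
      cols <- which(!is.na(aln$exon_index) & aln$exon_index == e)
      sub <- m[rows, cols, drop = FALSE]
      keep <- colMeans(sub == "-") <= 0.5       # drop gap-majority columns
      if (!any(keep))
        stop("exon ", e, " of paralog ", p, " has only gap columns")
      sub <- sub[, keep, drop = FALSE]
      L <- ncol(sub)
      pssm <- matrix(0, 20L, L, dimnames = list(AA20, NULL))
      for (j in seq_len(L)) {
        res <- sub[, j]; res <- res[res %in% AA20]
        n <- length(res)
        cnt <- table(factor(res, levels = AA20))
        pssm[, j] <- log2(((as.numeric(cnt) + beta * bg) / (n + beta)) / bg)
      }
      colmax <- apply(pssm, 2, max)
      models[[length(models) + 1L]] <- structure(
        list(paralog = p, exon = e, pssm = pssm, length = L,
             colmax = colmax, max_score = sum(colmax),
             min_score = threshold_frac * sum(colmax),
             threshold_frac = threshold_frac,
             consensus = paste0(AA20[apply(pssm, 2, which.max)],
                                collapse = "")),
        class = "ExonModel")
    }
  }
  models
}

#' @export
print.ExonModel <- function(x, ...) {
  cat(sprintf("ExonModel %s exon %d: %d columns, max %.2f bits (threshold %.2f)\n",
              x$paralog, x$exon, x$length, x$max_score, x$min_score))
  invisible(x)
}

#' Score a peptide under an exon model
#'
#' Per-column log-odds are summed; residues outside the 20 standard amino
#' acids (`X` from ambiguous codons, `*` stops, gaps) contribute 0 bits.
#'
#' @param model An `ExonModel`.
#' @param peptide Character string of length equal to the model.
#' @return Score in bits.
#' @export
score_peptide <- function(model, peptide) {
  stopifnot(nchar(peptide) == model$length)
  idx <- match(strsplit(peptide, "")[[1]], AA20)
  sum(model$pssm[cbind(idx, seq_len(model$length))], na.rm = TRUE)
}

# score all windows of a peptide index vector against pssm columns
# `cols`; returns vector over start positions 1..P-L+1
.window_scores <- function(pssm, cols, pepidx) {
  L <- length(cols)
  P <- length(pepidx)
  nw <- P - L + 1L
  if (nw < 1L) return(numeric(0))
  tot <- numeric(nw)
  for (j in seq_len(L)) {
    v <- unname(pssm[, cols[j]])[pepidx[j:(nw + j - 1L)]]
    v[is.na(v)] <- 0
    tot <- tot + v
  }
  tot
}

#' Scan contigs for exon hits in all six reading frames
#'
#' Every window whose score reaches the threshold is reported;
#' reverse-strand hits are reported in forward coordinates with strand
#' `"-"`. Windows in which more than `max_stop_frac` of codons are stops
#' are discarded (pseudogene exons with isolated stops remain detectable).
#' Overlapping hits of the same model on one contig are reduced to local
#' maxima. At contig edges, model prefixes/suffixes of at least
#' `min_partial_codons` columns are scored and emitted as `partial` hits
#' (exons split by assembly breakpoints).
#'
#' @param contigs Named character vector (or `DNAStringSet`) of contigs.
#' @param models List of `ExonModel` objects from [build_exon_models()].
#' @param threshold Absolute score threshold in bits applied to all models;
#'   `NULL` (default) uses each model's own `min_score`.
#' @param max_stop_frac Maximum fraction of stop codons tolerated per window.
#' @param min_partial_codons Minimum length of partial edge hits; `0`
#'   disables partial-hit emission.
#' @param min_hit_bits Absolute score floor in bits applied on top of any
#'   relative threshold; calibrated so random windows across a small genome
#'   essentially never reach it (standard practice for translated homology
#'   search over many windows).
#' @return `data.frame` of hits: `contig`, `start`, `end` (0-based
#'   half-open, forward strand), `strand`, `frame`, `paralog`, `exon`,
#'   `score`, `partial`.
#' @export
scan_contigs <- function(contigs, models, threshold = NULL,
                         max_stop_frac = 0.2, min_partial_codons = 10L,
                         min_hit_bits = 17) {
  if (!is.character(contigs)) contigs <- as.character(contigs)
  stopifnot(!is.null(names(contigs)))
  hits <- list()
  emit <- function(contig, start, end, strand, frame, model, score, partial) {
    hits[[length(hits) + 1L]] <<- data.frame(
      contig = contig, start = start, end = end, strand = strand,
      frame = frame, paralog = model$paralog, exon = model$exon,
      score = score, partial = partial)
  }
  for (cn in names(contigs)) {
    len <- nchar(contigs[[cn]])
    for (strand in c("+", "-")) {
      seq <- if (strand == "+") contigs[[cn]] else revcomp(contigs[[cn]])
      for (f in 0:2) {
        pep <- translate_dna(substr(seq, f + 1L, len))
        P <- nchar(pep)
        if (P == 0) next
        chars <- strsplit(pep, "")[[1]]
        pepidx <- match(chars, AA20)
        stop_cum <- c(0L, cumsum(chars == "*"))
        to_fwd <- function(w, ncod) {
          # window at peptide pos w spanning ncod codons -> forward coords
          s <- f + 3L * (w - 1L)
          e <- s + 3L * ncod
          if (strand == "+") c(s, e) else c(len - e, len - s)
        }
        for (model in models) {
          L <- model$length
          thr <- max(if (is.null(threshold)) model$min_score else threshold,
                     min_hit_bits)
          if (P >= L) {
            tot <- .window_scores(model$pssm, seq_len(L), pepidx)
            nstop <- stop_cum[seq_along(tot) + L] - stop_cum[seq_along(tot)]
            ok <- which(tot >= thr & nstop <= max_stop_frac * L)
            for (w in ok) {
              co <- to_fwd(w, L)
              emit(cn, co[1], co[2], strand, f, model, tot[w], FALSE)
            }
          }
          if (min_partial_codons > 0L && P >= min_partial_codons) {
            for (mlen in seq(min_partial_codons, min(L - 1L, P))) {
              # contig 5' edge in scan orientation: model suffix at pep pos 1
              cols <- (L - mlen + 1L):L
              sthr <- max(if (is.null(threshold))
                model$threshold_frac * sum(model$colmax[cols]) else
                  threshold * mlen / L, min_hit_bits)
              sc <- sum(model$pssm[cbind(pepidx[seq_len(mlen)], cols)],
                        na.rm = TRUE)
              nstop <- stop_cum[mlen + 1L] - stop_cum[1L]
              if (sc >= sthr && nstop <= max_stop_frac * mlen) {
                co <- to_fwd(1L, mlen)
                emit(cn, co[1], co[2], strand, f, model, sc, TRUE)
              }
              # contig 3' edge: model prefix ending at last peptide position
              cols <- seq_len(mlen)
              pthr <- max(if (is.null(threshold))
                model$threshold_frac * sum(model$colmax[cols]) else
                  threshold * mlen / L, min_hit_bits)
              w0 <- P - mlen + 1L
              sc <- sum(model$pssm[cbind(pepidx[w0:P], cols)], na.rm = TRUE)
              nstop <- stop_cum[P + 1L] - stop_cum[w0]
              if (sc >= pthr && nstop <= max_stop_frac * mlen) {
                co <- to_fwd(w0, mlen)
                emit(cn, co[1], co[2], strand, f, model, sc, TRUE)
              }
            }
          }
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame = integer(0), paralog = character(0),
                      exon = integer(0), score = numeric(0),
                      partial = logical(0)))
  h <- do.call(rbind, hits)
  .suppress_local_maxima(h)
}

# Reduce overlapping same-model hits on one contig to local maxima:
# greedy by descending score (ties: full before partial, then start).
.suppress_local_maxima <- function(h) {
  keep <- logical(nrow(h))
  key <- paste(h$paralog, h$exon, h$contig)
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(-h$score[idx], h$partial[idx], h$start[idx])]
    kept <- integer(0)
    for (i in idx) {
      if (!any(pmax(h$start[i], h$start[kept]) <
                 pmin(h$end[i], h$end[kept]))) {
        kept <- c(kept, i)
      }
    }
    keep[kept] <- TRUE
  }
  out <- h[keep, , drop = FALSE]
  out <- out[order(out$contig, out$start, out$paralog, out$exon), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Refine hit boundaries to canonical splice sites
#'
#' Moves each boundary by at most `window_nt` to the nearest position whose
#' flanking intronic dinucleotide is canonical — `AG` immediately upstream
#' of the exon (acceptor side) and `GT` immediately downstream (donor side)
#' — subject to the two shifts preserving the exon's coding phase (their
#' difference divisible by 3). Hits are left unchanged (and flagged) when no
#' candidate exists in the window.
#'
#' @param hit One row of the hit table from [scan_contigs()].
#' @param contig Sequence of the hit's contig.
#' @param window_nt Maximum boundary shift in nucleotides.
#' @return The hit row with possibly adjusted `start`/`end` and an added
#'   logical `refined` column.
#' @export
refine_splice_boundaries <- function(hit, contig, window_nt = 12L) {
  stopifnot(window_nt >= 0)
  if (window_nt == 0L) { hit$refined <- FALSE; return(hit) }
  len <- nchar(contig)
  plus <- hit$strand == "+"
  oseq <- if (plus) contig else revcomp(contig)
  os <- if (plus) hit$start else len - hit$end
  oe <- if (plus) hit$end else len - hit$start

  acc <- Filter(function(s) s >= 2 && s < oe &&
                  substr(oseq, s - 1L, s) == "AG",
                (os - window_nt):(os + window_nt))
  don <- Filter(function(e) e > os && e <= len - 2L &&
                  substr(oseq, e + 1L, e + 2L) == "GT",
                (oe - window_nt):(oe + window_nt))
  acc <- unlist(acc); don <- unlist(don)
  best <- NULL; bestmove <- Inf
  cand_s <- if (length(acc)) acc else os
  cand_e <- if (length(don)) don else oe
  for (s in cand_s) for (e in cand_e) {
    if ((e - s - (oe - os)) %% 3L != 0L) next
    move <- abs(s - os) + abs(e - oe)
    if (move < bestmove) { bestmove <- move; best <- c(s, e) }
  }
  if (is.null(best) || (!length(acc) && !length(don))) {
    hit$refined <- FALSE
    return(hit)
  }
  if (plus) {
    hit$start <- best[1]; hit$end <- best[2]
  } else {
    hit$start <- len - best[2]; hit$end <- len - best[1]
  }
  hit$refined <- bestmove > 0 || (length(acc) > 0 && length(don) > 0)
  hit
}
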