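# Specificity-determining position (SDP) detection by four complementary
# scorers with a two-of-four consensus, plus alignment filtering and the
# Karlin sum-of-pairs conservation profile. SDPs are alignment columns whose
# residue states discriminate functional subgroups of a protein family
# (e.g. recently duplicated paralog pairs).

#' Filter an alignment by coverage, redundancy and sequence length
#'
#' Sequences with a non-gap fraction at or below `min_coverage` are removed
#' first; then pairs above the `max_redundancy` identity threshold are
#' reduced greedily, keeping the first of each pair in input order; finally
#' an optional unaligned-length window is applied.
#'
#' @param aln A [curated_alignment()].
#' @param min_coverage Minimum fraction of non-gap columns (keep if
#'   coverage > this value); 0 disables.
#' @param max_redundancy Pairwise identity threshold (keep if
#'   identity < this value, computed on shared non-gap columns); 1 disables.
#' @param length_window Optional `c(min, max)` on unaligned length
#'   (keep if min < length < max).
#' @return Filtered [curated_alignment()]; errors (reporting per-rule
#'   removal counts) if nothing survives.
#' @export
filter_alignment <- function(aln, min_coverage = 0.7, max_redundancy = 0.98,
                             length_window = NULL) {
  stopifnot(inherits(aln, "CuratedAlignment"))
  m <- aln_matrix(aln)
  keep <- rep(TRUE, nrow(m))
  cov <- rowMeans(m != "-")
  n_cov <- sum(cov <= min_coverage)
  keep[cov <= min_coverage] <- FALSE
  # greedy redundancy removal in input order (threshold 1 disables)
  n_red <- 0L
  idx <- if (max_redundancy < 1) which(keep) else integer(0)
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (!keep[i]) next
    for (k in idx[seq_along(idx) > j]) {
      if (!keep[k]) next
      shared <- m[i, ] != "-" & m[k, ] != "-"
      if (!any(shared)) next
      ident <- mean(m[i, shared] == m[k, shared])
      if (ident >= max_redundancy) { keep[k] <- FALSE; n_red <- n_red + 1L }
    }
  }
  n_len <- 0L
  if (!is.null(length_window)) {
    len <- rowSums(m != "-")
    bad <- keep & !(len > length_window[1] & len < length_window[2])
    n_len <- sum(bad)
    keep[bad] <- FALSE
  }
  if (!any(keep))
    stop(sprintf(
      "no sequences left after filtering (removed: %d coverage, %d redundancy, %d length)",
      n_cov, n_red, n_len))
  curated_alignment(aln$seqs[keep], aln$groups[keep], aln$exon_index,
                    if (!is.null(aln$reference) &&
                          aln$reference %in% names(aln$seqs[keep]))
                      aln$reference else NULL)
}

# column residue frequency vector over 20 aa + gap
.col_freq <- function(chars) {
  symbols <- c(AA20, "-")
  tab <- table(factor(chars, levels = symbols))
  as.numeric(tab) / length(chars)
}

.jsd2 <- function(p, q) {
  # Jensen-Shannon divergence, base 2 (bounded by 1)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

#' Sequence-harmony style group separation score
#'
#' Per column, the Jensen-Shannon divergence (base 2) between the residue
#' frequency distributions of the two groups (gaps as 21st symbol) is
#' complemented so that identical distributions score 1 and disjoint ones 0.
#' Z-scores are computed against the mean/sd of the scores across all
#' scorable columns; strongly separating columns thus have strongly negative
#' z-scores.
#'
#' @param aln A [curated_alignment()] with exactly two groups.
#' @return `data.frame` with columns `column`, `score`, `z`, `flagged`
#'   (all-gap columns, not scored).
#' @export
sequence_harmony <- function(aln) {
  stopifnot(inherits(aln, "CuratedAlignment"))
  g <- unique(aln$groups)
  if (length(g) != 2) stop("sequence_harmony requires exactly 2 groups")
  m <- aln_matrix(aln)
  a <- m[aln$groups == g[1], , drop = FALSE]
  b <- m[aln$groups == g[2], , drop = FALSE]
  score <- numeric(ncol(m)); flagged <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    if (all(m[, j] == "-")) { score[j] <- NA; flagged[j] <- TRUE; next }
    score[j] <- 1 - .jsd2(.col_freq(a[, j]), .col_freq(b[, j]))
  }
  # robust z: median/MAD, so a handful of strongly separating columns does
  # not inflate the scale and mask itself (mean/sd caps |z| near
  # sqrt(n_cols/n_outliers))
  mu <- stats::median(score, na.rm = TRUE)
  sdv <- stats::mad(score, na.rm = TRUE)
  if (!isTRUE(sdv > 0)) sdv <- stats::sd(score, na.rm = TRUE)
  z <- if (isTRUE(sdv > 0)) (score - mu) / sdv else rep(0, length(score))
  data.frame(column = seq_len(ncol(m)), score = score, z = z,
             flagged = flagged)
}

#' multi-RELIEF column weights
#'
#' RELIEF feature weighting with 0/1 residue-identity distance: for every
#' sequence, the nearest same-group neighbour (hit) and nearest other-group
#' neighbour (miss) under whole-sequence Hamming distance are found (ties
#' broken at random per iteration), and each column's weight accumulates
#' (miss mismatch − hit mismatch). Weights are averaged over iterations,
#' sequences, and — with more than two groups — over all group pairs, giving
#' values in [−1, 1]. A perfectly group-separating column scores 1; a fully
#' conserved column 0.
#'
#' @param aln A [curated_alignment()] with >= 2 groups.
#' @param n_iterations Number of resampling iterations.
#' @param seed Integer seed for tie-breaking (reproducible).
#' @return `data.frame` with columns `column`, `weight`.
#' @export
multi_relief <- function(aln, n_iterations = 10L, seed = 1L) {
  stopifnot(inherits(aln, "CuratedAlignment"), n_iterations >= 1)
  m <- aln_matrix(aln)
  groups <- aln$groups
  glev <- unique(groups)
  if (length(glev) < 2) stop("multi_relief requires >= 2 groups")
  with_seed(seed, {
    pair_weights <- list()
    for (gi in seq_along(glev)) for (gj in seq_along(glev)) {
      if (gi >= gj) next
      sel <- groups %in% glev[c(gi, gj)]
      sub <- m[sel, , drop = FALSE]
      sg <- groups[sel]
      if (min(table(sg)) < 2) {
        warning("group with < 2 sequences skipped: ",
                names(which.min(table(sg))))
        next
      }
      n <- nrow(sub)
      D <- matrix(0, n, n)
      for (i in seq_len(n - 1)) for (k in (i + 1):n) {
        d <- mean(sub[i, ] != sub[k, ])
        D[i, k] <- D[k, i] <- d
      }
      w <- numeric(ncol(sub))
      for (it in seq_len(n_iterations)) {
        for (i in seq_len(n)) {
          hits <- which(sg == sg[i]); hits <- hits[hits != i]
          misses <- which(sg != sg[i])
          nh <- hits[D[i, hits] == min(D[i, hits])]
          nm <- misses[D[i, misses] == min(D[i, misses])]
          nh <- if (length(nh) > 1) nh[sample.int(length(nh), 1)] else nh
          nm <- if (length(nm) > 1) nm[sample.int(length(nm), 1)] else nm
          w <- w + (sub[i, ] != sub[nm, ]) - (sub[i, ] != sub[nh, ])
        }
      }
      pair_weights[[length(pair_weights) + 1L]] <- w / (n_iterations * n)
    }
    if (!length(pair_weights)) stop("no scorable group pair")
    weight <- Reduce(`+`, pair_weights) / length(pair_weights)
    data.frame(column = seq_len(ncol(m)), weight = weight)
  })
}

#' Xdet mutational-behaviour correlation score
#'
#' Per column, the vector of pairwise residue similarities (over all sequence
#' pairs, under a substitution matrix) is rank-correlated with a binary
#' function matrix (1 for same-group pairs, 0 otherwise). Columns with zero
#' variance in either vector are flagged, not scored.
#'
#' @param aln A [curated_alignment()].
#' @param simmat Residue similarity matrix (default BLOSUM62).
#' @param funcmat Optional symmetric function matrix over sequences; default
#'   is the same-group indicator.
#' @param method Correlation method, `"spearman"` (default) or `"pearson"`.
#' @return `data.frame` with columns `column`, `score`, `flagged`.
#' @export
xdet <- function(aln, simmat = blosum62_matrix(), funcmat = NULL,
                 method = c("spearman", "pearson")) {
  stopifnot(inherits(aln, "CuratedAlignment"))
  method <- match.arg(method)
  m <- aln_matrix(aln)
  n <- nrow(m)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (is.null(funcmat)) {
    funcmat <- outer(aln$groups, aln$groups, `==`) * 1
  }
  if (!isTRUE(all.equal(funcmat, t(funcmat))))
    stop("function matrix must be symmetric")
  fv <- funcmat[pairs]
  score <- rep(NA_real_, ncol(m)); flagged <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    a1 <- m[pairs[, 1], j]; a2 <- m[pairs[, 2], j]
    ok <- a1 %in% AA20 & a2 %in% AA20
    if (sum(ok) < 3) { flagged[j] <- TRUE; next }
    sv <- simmat[cbind(a1[ok], a2[ok])]
    if (stats::sd(sv) == 0 || stats::sd(fv[ok]) == 0) {
      flagged[j] <- TRUE; next
    }
    score[j] <- stats::cor(sv, fv[ok], method = method)
  }
  data.frame(column = seq_len(ncol(m)), score = score, flagged = flagged)
}

#' Multiple correspondence analysis grouping and SDP flags
#'
#' Correspondence analysis of the binary residue-indicator matrix via
#' singular value decomposition of the standardized residuals. Sequences are
#' clustered on the leading axes (k-means; or taken from `labels` in
#' supervised mode). A column is flagged as specificity determining when one
#' of its residue states (with support of at least two sequences) projects
#' within the configured cosine threshold of a cluster centroid direction
#' and is confined to that cluster.
#'
#' @param aln A [curated_alignment()] with >= 4 sequences.
#' @param n_groups Number of clusters (default: number of distinct labels).
#' @param labels Optional supervision labels, one per sequence.
#' @param cosine Cosine threshold for flagging a column state.
#' @param seed Seed for k-means initialization.
#' @return List with `clusters` (named cluster id per sequence), `flags`
#'   (`data.frame` of `column`, `mca_flag`) and `axes` (row coordinates).
#' @export
mca_grouping <- function(aln, n_groups = NULL, labels = NULL, cosine = 0.9,
                         seed = 1L) {
  stopifnot(inherits(aln, "CuratedAlignment"))
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 4) stop("mca_grouping requires >= 4 sequences")
  if (is.null(n_groups))
    n_groups <- length(unique(if (!is.null(labels)) labels else aln$groups))
  # binary indicator matrix over observed (column, residue) states
  states <- list()
  for (j in seq_len(ncol(m))) {
    res <- unique(m[, j]); res <- res[res != "-"]
    for (r in res) {
      vec <- as.numeric(m[, j] == r)
      # singleton states carry no grouping signal but dominate the
      # chi-square scaling; exclude them from the geometry
      if (sum(vec) < 2) next
      states[[length(states) + 1L]] <- list(col = j, res = r, vec = vec)
    }
  }
  if (!length(states)) stop("no residue state with support >= 2")
  X <- vapply(states, `[[`, numeric(n), "vec")
  colnames(X) <- vapply(states, function(s) paste0(s$col, ":", s$res), "")
  # correspondence analysis of X
  P <- X / sum(X)
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cc) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  rank <- sum(sv$d > 1e-10)
  if (rank < n_groups - 1L)
    warning("degenerate geometry: rank supports only ", rank + 1L,
            " clusters")
  k <- max(1L, min(max(n_groups - 1L, 3L), rank))
  Frow <- diag(1 / sqrt(r)) %*% sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k)
  Gcol <- diag(1 / sqrt(cc)) %*% sv$v[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k)
  rownames(Frow) <- rownames(m)
  if (!is.null(labels)) {
    if (!is.null(names(labels))) labels <- labels[rownames(m)]
    clusters <- as.integer(factor(labels))
  } else {
    n_distinct <- nrow(unique(round(Frow, 12)))
    centers <- min(n_groups, n, n_distinct)
    clusters <- if (centers < 2) rep(1L, n) else with_seed(seed,
      stats::kmeans(Frow, centers = centers, nstart = 10)$cluster)
  }
  names(clusters) <- rownames(m)
  centroids <- do.call(rbind, lapply(sort(unique(clusters)), function(cl)
    colMeans(Frow[clusters == cl, , drop = FALSE])))
  cosab <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  }
  flag <- logical(ncol(m))
  for (s in seq_along(states)) {
    st <- states[[s]]
    support <- which(st$vec == 1)
    if (length(support) < 2) next
    cl <- clusters[support]
    if (length(unique(cl)) != 1) next          # state must be cluster-confined
    ci <- unique(cl)
    # a determining state characterizes its cluster, not a minority of it
    if (length(support) < 0.8 * sum(clusters == ci)) next
    if (cosab(Gcol[s, ], centroids[ci, ]) >= cosine)
      flag[st$col] <- TRUE
  }
  list(clusters = clusters,
       flags = data.frame(column = seq_len(ncol(m)), mca_flag = flag),
       axes = Frow)
}

#' Consensus specificity-determining positions
#'
#' A column is reported as specificity determining when at least two of the
#' four methods retrieve it at the configured cutoffs (defaults: SH z-score
#' < -6, multi-RELIEF weight > 0.7, Xdet score < 0.6, MCA flag). Columns are
#' reported in reference-residue numbering when the alignment designates a
#' reference row.
#'
#' @param aln A [curated_alignment()].
#' @param sh Result of [sequence_harmony()].
#' @param mr Result of [multi_relief()].
#' @param xd Result of [xdet()].
#' @param mca Result of [mca_grouping()].
#' @param cutoffs Named list overriding `sh_z`, `mr`, `xdet` cutoffs and
#'   `xdet_keep_below` polarity.
#' @return `data.frame` with one row per consensus column: `column`,
#'   `reference_position`, `n_methods`, and the per-method evidence flags.
#' @export
consensus_sdps <- function(aln, sh, mr, xd, mca,
                           cutoffs = list()) {
  cfg <- utils::modifyList(
    list(sh_z = -6, mr = 0.7, xdet = 0.6, xdet_keep_below = TRUE), cutoffs)
  nc <- aln$width
  hit_sh <- !is.na(sh$z) & sh$z < cfg$sh_z
  hit_mr <- !is.na(mr$weight) & mr$weight > cfg$mr
  hit_xd <- !is.na(xd$score) &
    (if (isTRUE(cfg$xdet_keep_below)) xd$score < cfg$xdet
     else xd$score > cfg$xdet)
  hit_mca <- mca$flags$mca_flag
  nm <- hit_sh + hit_mr + hit_xd + hit_mca
  refpos <- aln_reference_positions(aln)
  out <- data.frame(column = seq_len(nc), reference_position = refpos,
                    sh = hit_sh, multi_relief = hit_mr, xdet = hit_xd,
                    mca = hit_mca, n_methods = nm)
  out[out$n_methods >= 2, , drop = FALSE]
}

#' Karlin sum-of-pairs conservation profile
#'
#' Per column, the average over all non-gap residue pairs of the
#' substitution-matrix similarity normalized by the geometric mean of the
#' self-similarities: `s(a,b) / sqrt(s(a,a) s(b,b))`. Identical-residue
#' columns score exactly 1. Sequences with coverage at or below
#' `min_coverage` are excluded first; columns with fewer than two non-gap
#' residues are flagged, not scored.
#'
#' @param aln A [curated_alignment()].
#' @param simmat Symmetric similarity matrix with positive diagonal
#'   (default BLOSUM62).
#' @param min_coverage Sequence coverage filter applied before scoring
#'   (fraction of non-gap columns; 0 disables).
#' @return `data.frame` with columns `column`, `score`, `flagged`.
#' @export
karlin_conservation <- function(aln, simmat = blosum62_matrix(),
                                min_coverage = 0.9) {
  stopifnot(inherits(aln, "CuratedAlignment"))
  stopifnot(isTRUE(all.equal(simmat, t(simmat))), all(diag(simmat) > 0))
  if (min_coverage > 0) {
    m0 <- aln_matrix(aln)
    keep <- rowMeans(m0 != "-") > min_coverage
    if (!any(keep)) stop("no sequences above coverage filter")
    aln <- curated_alignment(aln$seqs[keep], aln$groups[keep],
                             aln$exon_index, NULL)
  }
  m <- aln_matrix(aln)
  norm <- simmat / sqrt(diag(simmat) %o% diag(simmat))
  score <- rep(NA_real_, ncol(m)); flagged <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    res <- m[, j]
    res <- res[res %in% AA20]
    if (length(res) < 2) { flagged[j] <- TRUE; next }
    pr <- which(upper.tri(matrix(0, length(res), length(res))),
                arr.ind = TRUE)
    score[j] <- mean(norm[cbind(res[pr[, 1]], res[pr[, 2]])])
  }
  data.frame(column = seq_len(ncol(m)), score = score, flagged = flagged)
}

#' Simulate a two-group alignment with planted SDP columns
#'
#' Generates a grouped protein alignment in which planted columns are fully
#' separating (one conserved residue per group, distinct between groups)
#' while the remaining columns carry a shared consensus residue at the given
#' identity level with random residues elsewhere.
#'
#' @param n_per_group Sequences per group.
#' @param n_columns Total alignment columns.
#' @param sdp_columns Column indices to plant as fully separating.
#' @param identity Background per-column identity level of noise columns.
#' @param seed Integer seed.
#' @return A [curated_alignment()] with groups `"A"` and `"B"`; the planted
#'   columns are recorded in the `"planted"` attribute.
#' @export
simulate_grouped_alignment <- function(n_per_group = 20L, n_columns = 300L,
                                       sdp_columns = NULL, identity = 0.7,
                                       seed = 1L) {
  with_seed(seed, {
    if (is.null(sdp_columns))
      sdp_columns <- sort(sample.int(n_columns, 10L))
    n <- 2L * n_per_group
    m <- matrix("", n, n_columns)
    for (j in seq_len(n_columns)) {
      if (j %in% sdp_columns) {
        ab <- sample(AA20, 2L)
        m[, j] <- rep(ab, each = n_per_group)
      } else {
        cons <- sample(AA20, 1L)
        pick <- stats::runif(n) < identity
        m[, j] <- ifelse(pick, cons, sample(AA20, n, replace = TRUE))
      }
    }
    seqs <- apply(m, 1, paste0, collapse = "")
    names(seqs) <- sprintf("%s%02d", rep(c("A", "B"), each = n_per_group),
                           c(seq_len(n_per_group), seq_len(n_per_group)))
    aln <- curated_alignment(seqs, rep(c("A", "B"), each = n_per_group))
    attr(aln, "planted") <- sdp_columns
    aln
  })
}

#' Run all four SDP scorers and the consensus rule
#'
#' Convenience wrapper: [sequence_harmony()], [multi_relief()], [xdet()],
#' [mca_grouping()], then [consensus_sdps()].
#'
#' @inheritParams consensus_sdps
#' @param aln A two-group [curated_alignment()].
#' @param seed Seed for the stochastic scorers.
#' @return As [consensus_sdps()].
#' @export
detect_sdps <- function(aln, cutoffs = list(), seed = 1L) {
  sh <- sequence_harmony(aln)
  mr <- multi_relief(aln, seed = seed)
  xd <- xdet(aln)
  mca <- mca_grouping(aln, seed = seed)
  consensus_sdps(aln, sh, mr, xd, mca, cutoffs = cutoffs)
}
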