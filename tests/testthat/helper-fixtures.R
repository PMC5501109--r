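# Shared fixtures and independent oracles used across test files.

# Exhaustive minimum-cost oracle for binary-character parsimony on a rooted
# tree: enumerates every labeling of internal nodes (and of unknown tips).
exhaustive_parsimony_cost <- function(tree, x, gain = 1, loss = 1,
                                      prior = NULL) {
  n_tip <- length(tree$tip.label)
  x <- x[tree$tip.label]
  internal <- (n_tip + 1):(n_tip + tree$Nnode)
  edges <- tree$edge
  unk <- which(is.na(x))
  leafcombos <- if (length(unk))
    as.matrix(expand.grid(rep(list(0:1), length(unk)))) else
      matrix(0L, 1, 0)
  combos <- as.matrix(expand.grid(rep(list(0:1), length(internal))))
  best <- Inf
  states <- numeric(n_tip + tree$Nnode)
  for (li in seq_len(nrow(leafcombos))) {
    xx <- x
    if (length(unk)) xx[unk] <- leafcombos[li, ]
    states[seq_len(n_tip)] <- xx
    for (ci in seq_len(nrow(combos))) {
      states[internal] <- combos[ci, ]
      a <- states[edges[, 1]]; b <- states[edges[, 2]]
      cost <- sum((a == 0 & b == 1) * gain + (a == 1 & b == 0) * loss)
      if (!is.null(prior)) {
        r <- states[n_tip + 1]
        cost <- cost + (prior == 0 && r == 1) * gain +
          (prior == 1 && r == 0) * loss
      }
      if (cost < best) best <- cost
    }
  }
  best
}

# count of internal labelings achieving the minimal cost (no unknown tips)
exhaustive_optimum_count <- function(tree, x, gain = 1, loss = 1,
                                     prior = NULL) {
  n_tip <- length(tree$tip.label)
  x <- x[tree$tip.label]
  internal <- (n_tip + 1):(n_tip + tree$Nnode)
  edges <- tree$edge
  combos <- as.matrix(expand.grid(rep(list(0:1), length(internal))))
  costs <- apply(combos, 1, function(cmb) {
    states <- numeric(n_tip + tree$Nnode)
    states[seq_len(n_tip)] <- x
    states[internal] <- cmb
    a <- states[edges[, 1]]; b <- states[edges[, 2]]
    cost <- sum((a == 0 & b == 1) * gain + (a == 1 & b == 0) * loss)
    if (!is.null(prior)) {
      r <- states[n_tip + 1]
      cost <- cost + (prior == 0 && r == 1) * gain +
        (prior == 1 && r == 0) * loss
    }
    cost
  })
  sum(costs == min(costs))
}

# random assignment-problem instance within the brute-force guard
random_assignment_instance <- function(max_hits = 12L, max_paralogs = 3L,
                                       max_copies = 2L) {
  npar <- sample.int(max_paralogs, 1)
  labels <- paste0("P", seq_len(npar))
  pars <- data.frame(label = labels,
                     n_exons = sample(2:5, npar, replace = TRUE))
  nh <- sample.int(max_hits, 1)
  par <- sample(labels, nh, replace = TRUE)
  ex <- vapply(par, function(p)
    sample.int(pars$n_exons[pars$label == p], 1), 0L)
  st <- sample(0:40, nh, replace = TRUE) * 3L
  hits <- data.frame(
    contig = paste0("c", sample.int(3, nh, replace = TRUE)),
    start = st, end = st + sample(c(9L, 15L, 21L), nh, replace = TRUE),
    strand = sample(c("+", "-"), nh, replace = TRUE),
    paralog = par, exon = ex,
    score = round(stats::runif(nh, 0.5, 10), 2))
  assignment_problem(hits, pars,
                     max_copies = sample.int(max_copies, 1),
                     penalty = stats::runif(1, 0, 3))
}

# nucleotide encoding of a peptide (first codon per residue)
encode_peptide <- function(pep) {
  gc <- Biostrings::GENETIC_CODE
  paste0(vapply(strsplit(pep, "")[[1]],
                function(a) names(gc)[gc == a][1], ""), collapse = "")
}

quiet_rtree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}
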