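# Maximum-parsimony reconstruction of binary character histories (intron
# presence, gene presence) on a rooted tree, plus the paralog-count census
# comparator. Characters are vectors over tree tips with values 0, 1 or NA
# (unknown); costs are per-event (0->1 gain, 1->0 loss).

# postorder list of internal nodes for an ape tree
.postorder_internal <- function(tree) {
  n_tip <- length(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "postorder")
  unique(ord$edge[, 1][ord$edge[, 1] > n_tip])
}

.children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

#' Sankoff parsimony for one binary character
#'
#' Dynamic programming over per-node state-cost vectors under asymmetric
#' gain/loss costs. Unknown cells (`NA`) contribute zero cost to both states.
#' One optimal labeling is materialized with a deterministic tie-break that
#' prefers the absent state (pushing gains tipward), and the exact number of
#' equally parsimonious labelings is counted. When `root_prior` is 0 or 1,
#' the tree is treated as hanging off a virtual ancestor in that state, and a
#' change on that virtual branch is counted as an event at the root.
#'
#' @param tree Rooted `ape::phylo` tree.
#' @param character Named vector over `tree$tip.label` with values 0/1/`NA`.
#' @param gain_cost,loss_cost Positive costs of a 0->1 and 1->0 change.
#' @param root_prior `0`, `1`, or `NULL` for no prior (free root state).
#' @return List of class `EventReconstruction` with elements `cost`
#'   (minimal total cost), `changes` (number of events in the materialized
#'   labeling), `events` (`data.frame` of `node`, `type`), `states` (named
#'   vector of node states for the materialized labeling), `n_optimal`
#'   (number of equally parsimonious labelings), `gain_range` (min/max number
#'   of gains over all optimal labelings) and the cost model used.
#' @export
sankoff_parsimony <- function(tree, character, gain_cost = 1, loss_cost = 1,
                              root_prior = 0L) {
  stopifnot(gain_cost > 0, loss_cost > 0)
  tips <- tree$tip.label
  if (is.null(names(character)) && length(character) == length(tips))
    names(character) <- tips
  missing <- setdiff(tips, names(character))
  if (length(missing))
    stop("taxon missing from character: ", paste(missing, collapse = ", "))
  x <- character[tips]

  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  # branch cost c[from_state+1, to_state+1]
  bc <- matrix(c(0, loss_cost, gain_cost, 0), 2, 2)

  S <- matrix(Inf, n_node, 2)            # min cost of subtree given state
  NOPT <- matrix(0, n_node, 2)           # count of optimal sub-labelings
  GMIN <- matrix(Inf, n_node, 2)         # min gains among optimal
  GMAX <- matrix(-Inf, n_node, 2)        # max gains among optimal
  for (i in seq_len(n_tip)) {
    if (is.na(x[i])) S[i, ] <- c(0, 0) else S[i, x[i] + 1L] <- 0
    NOPT[i, is.finite(S[i, ])] <- 1
    GMIN[i, is.finite(S[i, ])] <- 0
    GMAX[i, is.finite(S[i, ])] <- 0
  }
  for (v in .postorder_internal(tree)) {
    S[v, ] <- 0; NOPT[v, ] <- 1; GMIN[v, ] <- 0; GMAX[v, ] <- 0
    for (ch in .children(tree, v)) {
      for (s in 0:1) {
        opts <- bc[s + 1L, ] + S[ch, ]
        m <- min(opts)
        best <- which(opts == m)
        S[v, s + 1L] <- S[v, s + 1L] + m
        NOPT[v, s + 1L] <- NOPT[v, s + 1L] * sum(NOPT[ch, best])
        gadd <- (s == 0 & (0:1)[best] == 1)   # gain on this branch?
        GMIN[v, s + 1L] <- GMIN[v, s + 1L] +
          min(GMIN[ch, best] + gadd)
        GMAX[v, s + 1L] <- GMAX[v, s + 1L] +
          max(GMAX[ch, best] + gadd)
      }
    }
  }

  if (is.null(root_prior)) {
    rootS <- S[root, ]
    rg <- 0
  } else {
    stopifnot(root_prior %in% c(0L, 1L))
    rootS <- bc[root_prior + 1L, ] + S[root, ]
    rg <- root_prior
  }
  cost <- min(rootS)
  cand <- which(rootS == cost)
  n_optimal <- sum(NOPT[root, cand])
  root_gain <- if (!is.null(root_prior)) (rg == 0 & (0:1)[cand] == 1) else
    rep(FALSE, length(cand))
  gain_range <- c(min = min(GMIN[root, cand] + root_gain),
                  max = max(GMAX[root, cand] + root_gain))

  # materialize one optimal labeling: at ties prefer state 0 (tipward gains)
  states <- integer(n_node)
  states[root] <- (0:1)[cand][order((0:1)[cand])][1]
  stack <- root
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    for (ch in .children(tree, v)) {
      opts <- bc[states[v] + 1L, ] + S[ch, ]
      best <- which(opts == min(opts)) - 1L
      states[ch] <- sort(best)[1]        # prefer 0 on ties
      if (ch > n_tip) stack <- c(stack, ch)
    }
  }
  ev <- data.frame(node = integer(0), type = character(0))
  if (!is.null(root_prior) && states[root] != root_prior)
    ev <- rbind(ev, data.frame(node = root,
                               type = if (states[root] == 1) "gain" else "loss"))
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]
    if (states[a] != states[b])
      ev <- rbind(ev, data.frame(node = b,
                                 type = if (states[b] == 1) "gain" else "loss"))
  }
  nm <- c(tips, rep(NA_character_, tree$Nnode))
  if (!is.null(tree$node.label)) nm[(n_tip + 1):n_node] <- tree$node.label
  structure(list(cost = cost, changes = nrow(ev), events = ev,
                 states = stats::setNames(states, nm),
                 n_optimal = n_optimal, gain_range = gain_range,
                 cost_model = c(gain = gain_cost, loss = loss_cost),
                 root_prior = if (is.null(root_prior)) NA_integer_ else
                   root_prior),
            class = "EventReconstruction")
}

#' @export
print.EventReconstruction <- function(x, ...) {
  cat(sprintf(
    "EventReconstruction: cost %g, %d event(s) (%d optimal labeling(s))\n",
    x$cost, x$changes, x$n_optimal))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Count independent gains of a character
#'
#' Number of branches carrying a 0->1 change in the materialized optimal
#' labeling, together with the min/max over all equally parsimonious
#' labelings (so "gained k times independently" claims can cite the minimum).
#'
#' @param reconstruction Result of [sankoff_parsimony()].
#' @return List with `gains` (materialized labeling), `min`, `max`, and the
#'   root prior used.
#' @export
count_independent_gains <- function(reconstruction) {
  stopifnot(inherits(reconstruction, "EventReconstruction"))
  g <- sum(reconstruction$events$type == "gain")
  list(gains = g,
       min = unname(reconstruction$gain_range["min"]),
       max = unname(reconstruction$gain_range["max"]),
       root_prior = reconstruction$root_prior)
}

#' Fitch minimum-change count for a binary character
#'
#' Classic Fitch downpass; unknown cells contribute the full state set.
#' Equals the Sankoff cost under unit gain/loss costs and a free root.
#'
#' @inheritParams sankoff_parsimony
#' @return Integer minimum number of changes.
#' @export
fitch_count <- function(tree, character) {
  tips <- tree$tip.label
  if (is.null(names(character)) && length(character) == length(tips))
    names(character) <- tips
  x <- character[tips]
  n_tip <- length(tips)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip))
    sets[[i]] <- if (is.na(x[i])) c(0L, 1L) else x[i]
  changes <- 0L
  for (v in .postorder_internal(tree)) {
    cur <- NULL
    for (ch in .children(tree, v)) {
      if (is.null(cur)) { cur <- sets[[ch]]; next }
      inter <- intersect(cur, sets[[ch]])
      if (length(inter)) cur <- inter
      else { cur <- union(cur, sets[[ch]]); changes <- changes + 1L }
    }
    sets[[v]] <- cur
  }
  changes
}

#' Dollo reconstruction of a binary character
#'
#' Single-origin model: exactly one gain at the most recent common ancestor
#' of all tips carrying the character, and the minimal number of losses below
#' it. Unknown cells are free and never force a loss.
#'
#' @inheritParams sankoff_parsimony
#' @return List of class `EventReconstruction` with `gain_node`, `losses`
#'   (`data.frame` of loss nodes), `changes` and `cost` (1 + number of
#'   losses; 0 if the character is absent everywhere).
#' @export
dollo_reconstruction <- function(tree, character) {
  tips <- tree$tip.label
  if (is.null(names(character)) && length(character) == length(tips))
    names(character) <- tips
  x <- character[tips]
  ones <- which(x == 1L)
  if (!length(ones)) {
    return(structure(list(cost = 0, changes = 0L, gain_node = NA_integer_,
                          losses = data.frame(node = integer(0)),
                          events = data.frame(node = integer(0),
                                              type = character(0))),
                     class = "EventReconstruction"))
  }
  n_tip <- length(tips)
  mrca <- if (length(ones) == 1L) ones else ape::getMRCA(tree, tips[ones])
  # has_one[v]: subtree of v contains a known 1; has_known[v]: any known cell
  n_node <- n_tip + tree$Nnode
  has_one <- logical(n_node); has_known <- logical(n_node)
  has_one[seq_len(n_tip)] <- !is.na(x) & x == 1L
  has_known[seq_len(n_tip)] <- !is.na(x)
  for (v in .postorder_internal(tree)) {
    ch <- .children(tree, v)
    has_one[v] <- any(has_one[ch])
    has_known[v] <- any(has_known[ch])
  }
  # walk subtree of mrca; a loss sits on the branch to each maximal subtree
  # with known cells but no known 1
  losses <- integer(0)
  stack <- mrca
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    for (ch in .children(tree, v)) {
      if (!has_one[ch] && has_known[ch]) losses <- c(losses, ch)
      else if (ch > n_tip) stack <- c(stack, ch)
    }
  }
  ev <- rbind(data.frame(node = mrca, type = "gain"),
              if (length(losses)) data.frame(node = losses, type = "loss"))
  structure(list(cost = 1 + length(losses), changes = nrow(ev),
                 gain_node = mrca, losses = data.frame(node = losses),
                 events = ev),
            class = "EventReconstruction")
}

#' Compare paralog counts between two annotation sources
#'
#' Given per-species paralog counts from a curated annotation and from a
#' reference database, tallies species where the curated count is higher,
#' lower, or equal, and the percentage of discrepant species (rounded half
#' up to integer percent).
#'
#' @param table `data.frame` with columns `species`, `curated`, `database`.
#' @return List with `n_higher`, `n_lower`, `n_equal`, `n_total`,
#'   `pct_discrepant`.
#' @export
census_compare <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("species", "curated", "database") %in% names(table)))
  if (nrow(table) == 0) stop("empty census table")
  if (anyDuplicated(table$species)) stop("duplicate species in census table")
  if (anyNA(table$curated) || anyNA(table$database))
    stop("species mismatch: missing counts in census table")
  hi <- sum(table$curated > table$database)
  lo <- sum(table$curated < table$database)
  eq <- sum(table$curated == table$database)
  list(n_higher = hi, n_lower = lo, n_equal = eq, n_total = nrow(table),
       pct_discrepant = round_half_up(100 * (hi + lo) / nrow(table)))
}
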