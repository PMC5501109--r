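# Step (2) of the two-step annotation procedure: globally assign exon hits
# scattered over contigs to paralogous gene copies by exact combinatorial
# optimization. Each hit may serve at most one copy; within a copy every
# family exon slot is used at most once, and hits sharing a contig must be
# non-overlapping and colinear (exon index increasing along the
# strand-oriented coordinate). The objective is the summed hit score minus a
# penalty per opened copy. The primary solver is an exact depth-first
# branch-and-bound with an admissible bound; a brute-force enumerator serves
# as an independent oracle.

#' Construct a paralog-to-contig assignment problem
#'
#' @param hits `data.frame` of exon hits with columns `contig`, `start`,
#'   `end` (0-based half-open, forward strand), `strand`, `paralog`, `exon`
#'   (1-based family exon index), `score` (bits); an optional logical
#'   `partial` column marks split-exon hits.
#' @param paralogs `data.frame` with columns `label` and `n_exons`.
#' @param max_copies Maximum number of copies per paralog (K).
#' @param penalty Score penalty (bits) for opening a copy.
#' @param contig_level If `TRUE`, all assigned hits of one contig must
#'   belong to the same copy (the coarser contig-to-paralog granularity).
#' @param allow_split_exon If `TRUE`, two `partial` hits of the same exon on
#'   different contigs may co-occupy one exon slot (exons split by assembly
#'   breakpoints).
#' @return Object of class `AssignmentProblem`.
#' @export
assignment_problem <- function(hits, paralogs, max_copies = 1L, penalty = 0,
                               contig_level = FALSE,
                               allow_split_exon = FALSE) {
  stopifnot(is.data.frame(hits), is.data.frame(paralogs),
            all(c("contig", "start", "end", "strand", "paralog", "exon",
                  "score") %in% names(hits)),
            all(c("label", "n_exons") %in% names(paralogs)),
            max_copies >= 1L, penalty >= 0, all(is.finite(hits$score)))
  if (!"partial" %in% names(hits)) hits$partial <- logical(nrow(hits))
  bad <- !hits$paralog %in% paralogs$label
  if (any(bad))
    stop("hit references unknown paralog model: ",
         paste(unique(hits$paralog[bad]), collapse = ", "))
  emax <- paralogs$n_exons[match(hits$paralog, paralogs$label)]
  if (any(hits$exon < 1 | hits$exon > emax))
    stop("hit exon index outside paralog model range")
  rownames(hits) <- NULL
  structure(list(hits = hits, paralogs = paralogs,
                 max_copies = as.integer(max_copies), penalty = penalty,
                 contig_level = contig_level,
                 allow_split_exon = allow_split_exon),
            class = "AssignmentProblem")
}

# Can hits i and j coexist in the same copy? (colinearity + overlap rule)
.pair_compatible <- function(h, i, j, allow_split_exon = FALSE) {
  if (h$exon[i] == h$exon[j]) {
    return(allow_split_exon && isTRUE(h$partial[i]) && isTRUE(h$partial[j]) &&
             h$contig[i] != h$contig[j])
  }
  if (h$contig[i] != h$contig[j]) return(TRUE)
  if (h$strand[i] != h$strand[j]) return(FALSE)
  if (max(h$start[i], h$start[j]) < min(h$end[i], h$end[j])) return(FALSE)
  along <- if (h$strand[i] == "+") h$start[i] < h$start[j] else
    h$start[i] > h$start[j]
  along == (h$exon[i] < h$exon[j])
}

# Admissible upper bound on the score obtainable from each suffix of the
# processing order: per contig, the max-weight set of pairwise
# non-overlapping hit intervals (weighted interval scheduling DP) — any
# feasible assignment selects non-overlapping hits per contig, and copy-open
# penalties only subtract.
.suffix_bounds <- function(h, ord) {
  n <- length(ord)
  vapply(seq_len(n), function(pos) {
    idx <- ord[pos:n]
    total <- 0
    for (ct in unique(h$contig[idx])) {
      sel <- idx[h$contig[idx] == ct]
      o <- sel[order(h$end[sel])]
      s <- h$start[o]; e <- h$end[o]; w <- h$score[o]
      m <- length(o)
      dp <- numeric(m + 1L)
      for (i in seq_len(m)) {
        # last interval (in end order) ending at or before s[i]
        p <- findInterval(s[i], e)
        dp[i + 1L] <- max(dp[i], w[i] + dp[p + 1L])
      }
      total <- total + dp[m + 1L]
    }
    total
  }, numeric(1))
}

# Do hits i and j overlap on the same contig? Overlapping hits describe the
# same genomic locus and are mutually exclusive across all copies: a locus
# encodes one exon of one gene (split-exon co-occupancy lives on different
# contigs by construction).
.pair_excludes <- function(h, i, j) {
  h$contig[i] == h$contig[j] &&
    max(h$start[i], h$start[j]) < min(h$end[i], h$end[j])
}

# Precompute the within-copy compatibility matrix for same-paralog hit pairs.
.compat_matrix <- function(problem) {
  h <- problem$hits
  n <- nrow(h)
  C <- matrix(TRUE, n, n)
  if (n < 2) return(C)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (h$paralog[i] != h$paralog[j]) next  # never share a copy anyway
    C[i, j] <- C[j, i] <-
      .pair_compatible(h, i, j, problem$allow_split_exon)
  }
  C
}

# Precompute the global mutual-exclusion matrix (overlap on one contig).
.exclude_matrix <- function(problem) {
  h <- problem$hits
  n <- nrow(h)
  X <- matrix(FALSE, n, n)
  if (n < 2) return(X)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    X[i, j] <- X[j, i] <- .pair_excludes(h, i, j)
  }
  X
}

#' Solve the paralog-to-contig assignment problem exactly
#'
#' Exact depth-first branch-and-bound: hits are processed in decreasing
#' score order; each hit is either assigned to an open (or the next fresh)
#' copy of its paralog, or left unassigned. Partial solutions are pruned
#' with the admissible bound "current objective + sum of remaining scores".
#' The problem is first split into independent connected components (shared
#' contig or shared paralog model) which are solved separately; the merged
#' solution is globally optimal.
#'
#' @param problem An [assignment_problem()].
#' @param decompose Solve connected components independently (default).
#' @return Object of class `AssignmentSolution`: `assignment` (per-hit copy
#'   key `"label#k"` or `NA`), `objective` (bits), `copies` (`data.frame` of
#'   opened copies with exon coverage and contig lists).
#' @export
solve_assignment <- function(problem, decompose = TRUE) {
  stopifnot(inherits(problem, "AssignmentProblem"))
  n <- nrow(problem$hits)
  if (n == 0)
    return(.make_solution(problem, rep(NA_character_, 0)))
  if (n * problem$max_copies > 1e5)
    stop("variable guard exceeded (", n * problem$max_copies,
         " > 1e5); partition the problem by connected component")
  if (decompose) {
    parts <- decompose_components(problem)
    if (length(parts) > 1) {
      assign_full <- rep(NA_character_, n)
      for (p in parts) {
        sub <- solve_assignment(p, decompose = FALSE)
        assign_full[attr(p, "hit_index")] <- sub$assignment
      }
      return(.make_solution(problem, assign_full))
    }
  }
  h <- problem$hits
  K <- problem$max_copies
  ord <- order(-h$score, h$paralog, h$contig, h$start)
  C <- .compat_matrix(problem)
  X <- .exclude_matrix(problem)
  suffix <- c(.suffix_bounds(h, ord), 0)

  best <- new.env(parent = emptyenv())
  best$obj <- 0                        # empty assignment is always feasible
  best$assign <- rep(NA_character_, n)

  copy_key <- function(p, k) paste0(p, "#", k)
  assign <- rep(NA_character_, n)      # copy key per hit (original index)
  copy_members <- list()               # key -> integer vector of hit indices
  n_open <- integer(0)                 # per paralog: number of open copies

  # contig-level mode: map contig -> copy key currently claiming it
  contig_claim <- list()

  feasible_add <- function(i, key) {
    taken <- which(!is.na(assign))
    if (length(taken) && any(X[i, taken])) return(FALSE)
    mem <- copy_members[[key]]
    if (!is.null(mem)) {
      if (!problem$allow_split_exon &&
            any(h$exon[mem] == h$exon[i])) return(FALSE)
      if (!all(C[i, mem])) return(FALSE)
    }
    if (problem$contig_level) {
      claim <- contig_claim[[h$contig[i]]]
      if (!is.null(claim) && claim != key) return(FALSE)
    }
    TRUE
  }

  recurse <- function(pos, obj) {
    if (pos > n) {
      if (obj > best$obj + 1e-9) {
        best$obj <- obj
        best$assign <- assign
      }
      return(invisible(NULL))
    }
    # admissible bound: all remaining hits taken, no further penalties
    if (obj + suffix[pos] <= best$obj + 1e-9) return(invisible(NULL))
    i <- ord[pos]
    p <- h$paralog[i]
    opened <- if (is.null(n_open[p]) || is.na(n_open[p])) 0L else n_open[p]
    kmax <- min(K, opened + 1L)
    for (k in seq_len(kmax)) {
      key <- copy_key(p, k)
      if (!feasible_add(i, key)) next
      new_copy <- k > opened
      assign[i] <<- key
      copy_members[[key]] <<- c(copy_members[[key]], i)
      if (new_copy) n_open[p] <<- k
      claimed <- FALSE
      if (problem$contig_level && is.null(contig_claim[[h$contig[i]]])) {
        contig_claim[[h$contig[i]]] <<- key; claimed <- TRUE
      }
      recurse(pos + 1L, obj + h$score[i] - if (new_copy) problem$penalty else 0)
      if (claimed) contig_claim[[h$contig[i]]] <<- NULL
      if (new_copy) n_open[p] <<- opened
      mem <- copy_members[[key]]
      copy_members[[key]] <<- mem[mem != i]
      assign[i] <<- NA_character_
    }
    recurse(pos + 1L, obj)             # leave hit unassigned
    invisible(NULL)
  }
  recurse(1L, 0)
  .make_solution(problem, best$assign)
}

# Build a canonical AssignmentSolution from a per-hit copy-key vector:
# renumber copies per paralog deterministically (by first contig/start of
# their hits) and compute objective and per-copy summaries.
.make_solution <- function(problem, assign) {
  h <- problem$hits
  keys <- unique(assign[!is.na(assign)])
  # deterministic copy renumbering within paralog
  if (length(keys)) {
    info <- do.call(rbind, lapply(keys, function(k) {
      mem <- which(assign == k)
      data.frame(key = k, paralog = h$paralog[mem[1]],
                 contig = min(h$contig[mem]),
                 start = min(h$start[mem]))
    }))
    info <- info[order(info$paralog, info$contig, info$start), ]
    remap <- character(0)
    for (p in unique(info$paralog)) {
      sel <- info$key[info$paralog == p]
      remap[sel] <- paste0(p, "#", seq_along(sel))
    }
    assign <- ifelse(is.na(assign), NA_character_, remap[assign])
    keys <- sort(unique(assign[!is.na(assign)]))
  }
  objective <- sum(h$score[!is.na(assign)]) - problem$penalty * length(keys)
  copies <- if (length(keys)) do.call(rbind, lapply(keys, function(k) {
    mem <- which(assign == k)
    p <- h$paralog[mem[1]]
    E <- problem$paralogs$n_exons[problem$paralogs$label == p]
    data.frame(copy = k, paralog = p,
               n_exons_found = length(unique(h$exon[mem])),
               n_exons_missing = E - length(unique(h$exon[mem])),
               exons = paste(sort(unique(h$exon[mem])), collapse = ","),
               contigs = paste(sort(unique(h$contig[mem])), collapse = ","),
               score = sum(h$score[mem]))
  })) else data.frame(copy = character(0), paralog = character(0),
                      n_exons_found = integer(0), n_exons_missing = integer(0),
                      exons = character(0), contigs = character(0),
                      score = numeric(0))
  structure(list(assignment = assign, objective = objective, copies = copies,
                 problem = problem),
            class = "AssignmentSolution")
}

#' @export
print.AssignmentSolution <- function(x, ...) {
  cat(sprintf("AssignmentSolution: %d/%d hits assigned to %d copies, objective %.3f bits\n",
              sum(!is.na(x$assignment)), length(x$assignment),
              nrow(x$copies), x$objective))
  if (nrow(x$copies)) print(x$copies[, c("copy", "n_exons_found",
                                         "n_exons_missing", "contigs")])
  invisible(x)
}

#' Brute-force assignment oracle
#'
#' Exhaustive enumeration over all assignment functions (each hit to one of
#' the K copies of its paralog or unassigned), with feasibility checked by a
#' direct validator. Optimal by construction; intended as an independent
#' cross-check for [solve_assignment()] on small instances.
#'
#' @param problem An [assignment_problem()] with at most `guard` hits.
#' @param guard Size guard on the number of hits.
#' @return An `AssignmentSolution`.
#' @export
brute_force_assignment <- function(problem, guard = 14L) {
  stopifnot(inherits(problem, "AssignmentProblem"))
  h <- problem$hits
  n <- nrow(h)
  if (n > guard) stop("brute-force guard exceeded: ", n, " > ", guard)
  K <- problem$max_copies
  best_obj <- 0
  best_assign <- rep(NA_character_, n)
  choice <- integer(n)                 # 0 = unassigned, 1..K = copy index

  ok_so_far <- function(upto) {
    i <- upto
    if (choice[i] == 0L) return(TRUE)
    for (j in seq_len(i - 1L)) {
      if (choice[j] == 0L) next
      if (h$contig[i] == h$contig[j] &&
            max(h$start[i], h$start[j]) < min(h$end[i], h$end[j]))
        return(FALSE)                  # one locus, one selected exon
      same_copy <- h$paralog[i] == h$paralog[j] && choice[i] == choice[j]
      if (same_copy) {
        if (h$exon[i] == h$exon[j] &&
              !(problem$allow_split_exon && isTRUE(h$partial[i]) &&
                  isTRUE(h$partial[j]) && h$contig[i] != h$contig[j]))
          return(FALSE)
        if (!.pair_compatible(h, i, j, problem$allow_split_exon) &&
              h$exon[i] != h$exon[j])
          return(FALSE)
      }
      if (problem$contig_level && h$contig[i] == h$contig[j] &&
            !(same_copy))
        return(FALSE)
    }
    TRUE
  }

  recurse <- function(pos) {
    if (pos > n) {
      used <- choice > 0L
      keys <- unique(paste0(h$paralog[used], "#", choice[used]))
      obj <- sum(h$score[used]) - problem$penalty * length(keys)
      if (obj > best_obj + 1e-9) {
        best_obj <<- obj
        best_assign <<- ifelse(choice > 0L,
                               paste0(h$paralog, "#", choice),
                               NA_character_)
      }
      return(invisible(NULL))
    }
    for (c in 0:K) {
      choice[pos] <<- c
      if (ok_so_far(pos)) recurse(pos + 1L)
    }
    choice[pos] <<- 0L
    invisible(NULL)
  }
  recurse(1L)
  .make_solution(problem, best_assign)
}

#' Split an assignment problem into independent components
#'
#' Hits are connected when they share a contig or a paralog model; connected
#' components can be solved independently and merged without loss of
#' optimality.
#'
#' @param problem An [assignment_problem()].
#' @return List of sub-problems; each carries its original hit indices in
#'   the `"hit_index"` attribute.
#' @export
decompose_components <- function(problem) {
  h <- problem$hits
  n <- nrow(h)
  if (n == 0) return(list(problem))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  edges <- integer(0)
  for (key in c("contig", "paralog")) {
    for (v in unique(h[[key]])) {
      mem <- which(h[[key]] == v)
      if (length(mem) > 1)
        edges <- c(edges, rbind(mem[-length(mem)], mem[-1]))
    }
  }
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  lapply(seq_len(max(comp)), function(ci) {
    sel <- which(comp == ci)
    sub <- assignment_problem(
      h[sel, , drop = FALSE],
      problem$paralogs[problem$paralogs$label %in% h$paralog[sel], ,
                       drop = FALSE],
      max_copies = problem$max_copies, penalty = problem$penalty,
      contig_level = problem$contig_level,
      allow_split_exon = problem$allow_split_exon)
    attr(sub, "hit_index") <- sel
    sub
  })
}

#' Validate the feasibility invariants of an assignment solution
#'
#' Independent post-hoc check: per-copy exon uniqueness, within-contig
#' colinearity/non-overlap, copy count within K, and objective consistency.
#'
#' @param solution An `AssignmentSolution`.
#' @return Invisibly `TRUE`; errors on violation.
#' @export
validate_solution <- function(solution) {
  problem <- solution$problem
  h <- problem$hits
  a <- solution$assignment
  sel <- which(!is.na(a))
  if (length(sel) > 1) {
    for (ii in seq_len(length(sel) - 1)) for (jj in (ii + 1):length(sel)) {
      i <- sel[ii]; j <- sel[jj]
      if (h$contig[i] == h$contig[j] &&
            max(h$start[i], h$start[j]) < min(h$end[i], h$end[j]))
        stop("overlapping hits both selected on contig ", h$contig[i])
    }
  }
  for (key in unique(a[!is.na(a)])) {
    mem <- which(a == key)
    ex <- h$exon[mem]
    if (!problem$allow_split_exon && anyDuplicated(ex))
      stop("exon slot used twice in copy ", key)
    if (length(mem) > 1) {
      for (ii in seq_len(length(mem) - 1)) for (jj in (ii + 1):length(mem)) {
        i <- mem[ii]; j <- mem[jj]
        if (h$exon[i] != h$exon[j] &&
              !.pair_compatible(h, i, j, problem$allow_split_exon))
          stop("colinearity/overlap violated in copy ", key)
      }
    }
  }
  k_per <- table(sub("#.*$", "", unique(a[!is.na(a)])))
  if (length(k_per) && any(k_per > problem$max_copies))
    stop("more than K copies opened")
  obj <- sum(h$score[!is.na(a)]) -
    problem$penalty * length(unique(a[!is.na(a)]))
  if (abs(obj - solution$objective) > 1e-9)
    stop("objective inconsistent with assignment")
  invisible(TRUE)
}

#' Convert an assignment solution into gene models
#'
#' One [gene_model()] per opened copy, exons ordered by family exon index,
#' with exons absent from the copy recorded as missing.
#'
#' @param solution An `AssignmentSolution`.
#' @param id_prefix Prefix for generated gene ids.
#' @return List of [gene_model()] objects.
#' @export
solution_to_gene_models <- function(solution, id_prefix = "gene") {
  problem <- solution$problem
  h <- problem$hits
  a <- solution$assignment
  models <- list()
  for (key in sort(unique(a[!is.na(a)]))) {
    mem <- which(a == key)
    p <- h$paralog[mem[1]]
    E <- problem$paralogs$n_exons[problem$paralogs$label == p]
    ex <- data.frame(contig = h$contig[mem], start = h$start[mem],
                     end = h$end[mem], strand = h$strand[mem],
                     exon_index = h$exon[mem])
    models[[length(models) + 1L]] <- gene_model(
      id = paste0(id_prefix, ".", key), label = p, exons = ex,
      missing_exons = setdiff(seq_len(E), ex$exon_index))
  }
  models
}
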