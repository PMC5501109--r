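simple_pars <- data.frame(label = "P", n_exons = 8L)

test_that("a single hit is assigned and scores the objective", {
  h <- data.frame(contig = "c1", start = 0L, end = 30L, strand = "+",
                  paralog = "P", exon = 1L, score = 5)
  s <- solve_assignment(assignment_problem(h, simple_pars))
  expect_equal(s$objective, 5)
  expect_false(is.na(s$assignment))
  expect_equal(nrow(s$copies), 1)
})

test_that("competing hits for one exon slot keep only the better one", {
  h <- data.frame(contig = c("c1", "c2"), start = 0L, end = 30L,
                  strand = "+", paralog = "P", exon = 3L,
                  score = c(4, 9))
  s <- solve_assignment(assignment_problem(h, simple_pars, max_copies = 1L))
  expect_equal(s$objective, 9)
  expect_true(is.na(s$assignment[1]) && !is.na(s$assignment[2]))
})

test_that("one copy is assembled across contigs from fragmented exons", {
  h <- data.frame(contig = c(rep("cA", 3), rep("cB", 5)),
                  start = c(0, 100, 200, 0, 100, 200, 300, 400),
                  end = c(30, 130, 230, 30, 130, 230, 330, 430),
                  strand = "+", paralog = "P", exon = 1:8,
                  score = 5)
  s <- solve_assignment(assignment_problem(h, simple_pars, penalty = 2))
  expect_equal(nrow(s$copies), 1)
  expect_equal(s$copies$n_exons_missing, 0)
  expect_setequal(strsplit(s$copies$contigs, ",")[[1]], c("cA", "cB"))
  g <- solution_to_gene_models(s)
  expect_length(g, 1)
  expect_equal(g[[1]]$exons$exon_index, 1:8)
  expect_length(g[[1]]$missing_exons, 0)
})

test_that("an overlapping, colinearity-violating pair keeps exactly one hit", {
  h <- data.frame(contig = "c1", start = c(0L, 10L), end = c(30L, 40L),
                  strand = "+", paralog = "P", exon = c(5L, 2L),
                  score = c(3, 7))
  for (solver in list(solve_assignment, brute_force_assignment)) {
    s <- solver(assignment_problem(h, simple_pars))
    expect_equal(sum(!is.na(s$assignment)), 1)
    expect_equal(s$objective, 7)
  }
})

test_that("empty problems yield the empty solution", {
  h <- data.frame(contig = character(0), start = integer(0),
                  end = integer(0), strand = character(0),
                  paralog = character(0), exon = integer(0),
                  score = numeric(0))
  p <- assignment_problem(h, simple_pars)
  expect_equal(solve_assignment(p)$objective, 0)
  expect_equal(brute_force_assignment(p)$objective, 0)
})

test_that("branch-and-bound equals brute force on random instances", {
  withr::with_seed(101, {
    for (i in 1:60) {
      pr <- random_assignment_instance()
      s1 <- solve_assignment(pr)
      s2 <- brute_force_assignment(pr)
      expect_equal(s1$objective, s2$objective, tolerance = 1e-9)
      expect_silent(validate_solution(s1))
    }
  })
})

test_that("raising the copy-open penalty never opens more copies", {
  withr::with_seed(202, {
    for (i in 1:20) {
      pr <- random_assignment_instance()
      n_prev <- Inf
      for (pen in c(0, 1, 3, 8, 20)) {
        pr2 <- assignment_problem(pr$hits, pr$paralogs,
                                  max_copies = pr$max_copies, penalty = pen)
        n <- nrow(solve_assignment(pr2)$copies)
        expect_lte(n, n_prev)
        n_prev <- n
      }
    }
  })
})

test_that("connected components solve independently with equal objective", {
  h <- data.frame(contig = c("c1", "c2"), start = 0L, end = 30L,
                  strand = "+", paralog = c("P", "Q"), exon = 1L,
                  score = c(4, 6))
  p <- assignment_problem(h, data.frame(label = c("P", "Q"), n_exons = 2L))
  parts <- decompose_components(p)
  expect_length(parts, 2)
  expect_length(decompose_components(parts[[1]]), 1)
  withr::with_seed(303, {
    for (i in 1:30) {
      pr <- random_assignment_instance()
      whole <- solve_assignment(pr, decompose = FALSE)$objective
      merged <- sum(vapply(decompose_components(pr), function(sub)
        solve_assignment(sub, decompose = FALSE)$objective, numeric(1)))
      expect_equal(whole, merged, tolerance = 1e-9)
    }
  })
})

test_that("re-solving a solution's induced subproblem returns the objective", {
  withr::with_seed(404, {
    for (i in 1:10) {
      pr <- random_assignment_instance()
      s <- solve_assignment(pr)
      sel <- which(!is.na(s$assignment))
      if (!length(sel)) next
      pr2 <- assignment_problem(pr$hits[sel, , drop = FALSE], pr$paralogs,
                                max_copies = pr$max_copies,
                                penalty = pr$penalty)
      expect_equal(solve_assignment(pr2)$objective, s$objective,
                   tolerance = 1e-9)
    }
  })
})

test_that("copies with missing exons are reported as incomplete", {
  h <- data.frame(contig = "c1", start = c(0, 100, 200),
                  end = c(30, 130, 230), strand = "+", paralog = "P",
                  exon = c(1L, 2L, 3L), score = 5)
  s <- solve_assignment(assignment_problem(h, simple_pars))
  g <- solution_to_gene_models(s)[[1]]
  expect_length(g$missing_exons, 5)
  expect_setequal(g$missing_exons, 4:8)
})

test_that("hit validation rejects unknown models and bad exon indices", {
  h <- data.frame(contig = "c1", start = 0L, end = 30L, strand = "+",
                  paralog = "Z", exon = 1L, score = 1)
  expect_error(assignment_problem(h, simple_pars), "unknown paralog")
  h$paralog <- "P"; h$exon <- 99L
  expect_error(assignment_problem(h, simple_pars), "exon index")
})
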