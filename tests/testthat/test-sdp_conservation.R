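test_that("alignment filters drop low-coverage and redundant sequences", {
  seqs <- c(full1 = "MKWVDEQRHL", full2 = "MKWVDEQRHL",
            part = "MKW-------", other = "QQWADEQRHL")
  aln <- curated_alignment(seqs, stats::setNames(rep("g", 4), names(seqs)))
  f <- filter_alignment(aln, min_coverage = 0.7, max_redundancy = 0.98)
  expect_false("part" %in% names(f$seqs))      # 30% coverage removed
  expect_false("full2" %in% names(f$seqs))     # identical duplicate removed
  expect_true(all(c("full1", "other") %in% names(f$seqs)))
  # min_coverage 0 and max_redundancy 1 disable both rules: identity
  f0 <- filter_alignment(aln, min_coverage = 0, max_redundancy = 1)
  expect_identical(f0$seqs, aln$seqs)
  # length window applied to unaligned lengths
  f1 <- filter_alignment(aln, min_coverage = 0, max_redundancy = 1,
                         length_window = c(5, 20))
  expect_false("part" %in% names(f1$seqs))
  expect_error(filter_alignment(aln, min_coverage = 1),
               "no sequences left")
})

test_that("sequence harmony scores identical 1, disjoint 0, mixed by formula", {
  seqs <- c(a1 = "AAK", a2 = "AAR", b1 = "AKK", b2 = "AKR")
  aln <- curated_alignment(seqs, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  sh <- sequence_harmony(aln)
  expect_equal(sh$score[1], 1)                  # all A in both groups
  expect_equal(sh$score[2], 0)                  # A vs K fully separating
  # column 3: both groups half K half R -> identical distributions
  expect_equal(sh$score[3], 1)
  # hand-computed JSD for an asymmetric column
  seqs2 <- c(a1 = "A", a2 = "A", b1 = "A", b2 = "K")
  aln2 <- curated_alignment(seqs2, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  pa <- c(1, 0); pb <- c(0.5, 0.5); m <- (pa + pb) / 2
  kl <- function(p, q) sum(ifelse(p > 0, p * log2(p / q), 0))
  expect_equal(sequence_harmony(aln2)$score[1],
               1 - (kl(pa, m) + kl(pb, m)) / 2, tolerance = 1e-12)
  # all-gap columns are flagged, not scored
  seqs3 <- c(a1 = "A-", a2 = "A-", b1 = "K-", b2 = "K-")
  sh3 <- sequence_harmony(curated_alignment(
    seqs3, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")))
  expect_true(sh3$flagged[2])
  expect_true(is.na(sh3$score[2]))
})

test_that("multi-RELIEF weights equal the exhaustive neighbour computation", {
  # designed so every nearest hit/miss is unique: weights are deterministic
  seqs <- c(s1 = "AAAAA", s2 = "AAAAT", s3 = "KKKAA", s4 = "KKKAT")
  aln <- curated_alignment(seqs, c(s1 = "g1", s2 = "g1",
                                   s3 = "g2", s4 = "g2"))
  mr <- multi_relief(aln, n_iterations = 3, seed = 1)
  expect_equal(mr$weight, c(1, 1, 1, 0, -1))
  # fully separating -> 1; conserved -> 0; within-group-varying -> negative
})

test_that("multi-RELIEF warns on singleton groups and stays in [-1, 1]", {
  seqs <- c(s1 = "AK", s2 = "AR", s3 = "KA")
  aln <- curated_alignment(seqs, c(s1 = "g1", s2 = "g1", s3 = "g2"))
  expect_warning(try(multi_relief(aln, seed = 1), silent = TRUE),
                 "skipped")
  big <- simulate_grouped_alignment(n_per_group = 6, n_columns = 40,
                                    sdp_columns = c(5, 6), seed = 3)
  w <- multi_relief(big, seed = 2)$weight
  expect_true(all(w >= -1 - 1e-12 & w <= 1 + 1e-12))
})

test_that("Xdet correlates similarity with group membership", {
  seqs <- c(a1 = "AKW", a2 = "AKW", b1 = "ARW", b2 = "ARW")
  aln <- curated_alignment(seqs, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  xd <- xdet(aln)
  # column 2 separates the groups: within-pair similarity (K/K, R/R) high,
  # across low -> strong positive rank correlation
  expect_gt(xd$score[2], 0.8)
  # fully conserved columns have zero variance: flagged, not scored
  expect_true(xd$flagged[1])
  expect_true(is.na(xd$score[1]))
  expect_error(xdet(aln, funcmat = matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("Xdet scores of random columns average to zero over permutations", {
  withr::with_seed(31, {
    n <- 10
    col <- sample(exonweaver:::AA20, n, replace = TRUE)
    seqs <- stats::setNames(col, paste0("s", 1:n))
    scores <- replicate(300, {
      groups <- sample(rep(c("A", "B"), each = n / 2))
      names(groups) <- names(seqs)
      xdet(curated_alignment(seqs, groups))$score[1]
    })
    se <- stats::sd(scores, na.rm = TRUE) / sqrt(sum(!is.na(scores)))
    expect_lt(abs(mean(scores, na.rm = TRUE)), 3 * se + 1e-6)
  })
})

test_that("MCA recovers planted groups and flags only their columns", {
  # groups differ at 10 planted columns and are identical elsewhere
  aln <- simulate_grouped_alignment(n_per_group = 10, n_columns = 60,
                                    sdp_columns = seq(5, 50, by = 5),
                                    identity = 1, seed = 41)
  m <- mca_grouping(aln, n_groups = 2, seed = 1)
  grp <- aln$groups
  expect_equal(length(unique(m$clusters[grp == "A"])), 1)
  expect_equal(length(unique(m$clusters[grp == "B"])), 1)
  expect_false(m$clusters[grp == "A"][1] == m$clusters[grp == "B"][1])
  expect_true(all(m$flags$mca_flag[seq(5, 50, by = 5)]))
  # supervised mode with the true labels gives the same flags
  ms <- mca_grouping(aln, labels = grp, seed = 1)
  expect_identical(m$flags, ms$flags)
  # identical sequences: one cluster, no flags
  same <- curated_alignment(stats::setNames(rep("MKWV", 4), paste0("s", 1:4)),
                            stats::setNames(rep(c("A", "B"), 2),
                                            paste0("s", 1:4)))
  m0 <- suppressWarnings(mca_grouping(same, n_groups = 2, seed = 1))
  expect_equal(length(unique(m0$clusters)), 1)
  expect_equal(sum(m0$flags$mca_flag), 0)
})

test_that("consensus requires at least two of the four methods", {
  aln <- simulate_grouped_alignment(n_per_group = 8, n_columns = 50,
                                    sdp_columns = c(7, 21), seed = 51)
  sh <- sequence_harmony(aln)
  mr <- multi_relief(aln, seed = 1)
  xd <- xdet(aln)
  mca <- mca_grouping(aln, seed = 1)
  out <- consensus_sdps(aln, sh, mr, xd, mca)
  expect_true(all(c(7, 21) %in% out$column))
  expect_true(all(out$n_methods >= 2))
  # a column flagged by a single method only is excluded
  mca_only <- mca
  mca_only$flags$mca_flag[] <- FALSE
  mca_only$flags$mca_flag[33] <- TRUE
  sh0 <- sh; sh0$z[] <- 0
  mr0 <- mr; mr0$weight[] <- 0
  xd0 <- xd; xd0$score[] <- 0.9
  out2 <- consensus_sdps(aln, sh0, mr0, xd0, mca_only)
  expect_false(33 %in% out2$column)
  # impossible cutoffs yield an empty set
  out3 <- consensus_sdps(aln, sh, mr, xd, mca,
                         cutoffs = list(sh_z = -1e9, mr = 2, xdet = -22,
                                        xdet_keep_below = TRUE))
  # mca alone cannot reach the 2-method rule
  expect_equal(nrow(out3), 0)
})

test_that("SH and multi-RELIEF rank separating above conserved columns alike", {
  aln <- simulate_grouped_alignment(n_per_group = 10, n_columns = 80,
                                    sdp_columns = c(5, 15, 25), seed = 61)
  # force three fully conserved columns
  seqs <- aln$seqs
  for (j in 40:42) substr(seqs, j, j) <- "W"
  aln <- curated_alignment(seqs, aln$groups)
  sh <- sequence_harmony(aln)
  mr <- multi_relief(aln, seed = 1)
  subset <- c(5, 15, 25, 40:42)
  r <- stats::cor(-sh$score[subset], mr$weight[subset], method = "spearman")
  expect_equal(r, 1)
})

test_that("Karlin conservation matches hand-computed pair averages", {
  aln <- curated_alignment(c(a = "AAW", b = "AAW", c = "VAW"),
                           groups = c(a = "x", b = "x", c = "y"))
  prof <- karlin_conservation(aln, min_coverage = 0)
  B <- blosum62_matrix()
  hand <- (B["A", "A"] / B["A", "A"] +
             2 * B["A", "V"] / sqrt(B["A", "A"] * B["V", "V"])) / 3
  expect_equal(prof$score[1], hand, tolerance = 1e-12)
  expect_equal(prof$score[2], 1)
  expect_equal(prof$score[3], 1)
  # permuting rows leaves the profile unchanged
  aln2 <- curated_alignment(aln$seqs[c(3, 1, 2)], aln$groups[c(3, 1, 2)])
  expect_equal(karlin_conservation(aln2, min_coverage = 0)$score,
               prof$score)
  # columns with < 2 non-gap residues are flagged
  aln3 <- curated_alignment(c(a = "A-", b = "--", c = "--"),
                            groups = c(a = "x", b = "x", c = "y"))
  prof3 <- karlin_conservation(aln3, min_coverage = 0)
  expect_true(all(prof3$flagged))
})

test_that("the coverage filter excludes gappy sequences before scoring", {
  seqs <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA", c = "VV--------")
  aln <- curated_alignment(seqs, stats::setNames(rep("g", 3), names(seqs)))
  prof <- karlin_conservation(aln, min_coverage = 0.9)
  # sequence c (20% coverage) is excluded: all columns fully conserved
  expect_true(all(prof$score[!prof$flagged] == 1))
})

test_that("all-gap padding columns are flagged by every scorer", {
  seqs <- c(a1 = "AK-", a2 = "AK-", b1 = "AR-", b2 = "AR-")
  aln <- curated_alignment(seqs, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_true(sequence_harmony(aln)$flagged[3])
  expect_true(xdet(aln)$flagged[3])
  expect_true(karlin_conservation(aln, min_coverage = 0)$flagged[3])
  expect_equal(multi_relief(aln, seed = 1)$weight[3], 0)
})
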