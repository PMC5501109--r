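# two identical rows per group, one exon of length 4
toy_alignment <- function(pep = "MKWV", groups = c(a = "P", b = "P")) {
  curated_alignment(stats::setNames(rep(pep, 2), names(groups)), groups,
                    exon_index = rep(1L, nchar(pep)))
}

test_that("model consensus maximizes the score by construction", {
  m <- build_exon_models(toy_alignment())[[1]]
  expect_equal(m$length, 4)
  expect_equal(m$consensus, "MKWV")
  expect_equal(score_peptide(m, "MKWV"), m$max_score, tolerance = 1e-9)
  withr::with_seed(5, {
    for (i in 1:25) {
      other <- paste0(sample(c("A", "R", "N", "D", "M", "K", "W", "V"), 4,
                             replace = TRUE), collapse = "")
      expect_lte(score_peptide(m, other), m$max_score + 1e-9)
    }
  })
})

test_that("peptide scores equal the hand-summed per-column log-odds", {
  aln <- curated_alignment(c(a = "MKW", b = "MAW", c = "QKW"),
                           groups = c(a = "P", b = "P", c = "P"),
                           exon_index = rep(1L, 3))
  beta <- 0.1
  m <- build_exon_models(aln, beta = beta)[[1]]
  bg <- exonweaver:::BLOSUM62_BACKGROUND
  hand <- function(pep) {
    cols <- list(c(M = 2, Q = 1), c(K = 2, A = 1), c(W = 3))
    s <- 0
    for (j in 1:3) {
      a <- substr(pep, j, j)
      cnt <- if (a %in% names(cols[[j]])) cols[[j]][[a]] else 0
      s <- s + log2(((cnt + beta * bg[[a]]) / (3 + beta)) / bg[[a]])
    }
    s
  }
  for (pep in c("MKW", "MAW", "QKW", "AAA", "WKM"))
    expect_equal(score_peptide(m, pep), hand(pep), tolerance = 1e-12)
})

test_that("uniform background and uniform column give zero bits", {
  # all 20 residues once per column, uniform background
  rows <- vapply(1:20, function(i)
    paste0(exonweaver:::AA20[(seq_len(3) + i - 2) %% 20 + 1],
           collapse = ""), "")
  names(rows) <- paste0("s", 1:20)
  aln <- curated_alignment(rows, stats::setNames(rep("P", 20), names(rows)),
                           exon_index = rep(1L, 3))
  unif <- stats::setNames(rep(1 / 20, 20), exonweaver:::AA20)
  m <- build_exon_models(aln, background = unif)[[1]]
  expect_equal(max(abs(m$pssm)), 0, tolerance = 1e-12)
})

test_that("an exact consensus encoding is found at [0, 3L) with max score", {
  m <- build_exon_models(toy_alignment("MKWVDE"))[[1]]
  contig <- c(c1 = encode_peptide(m$consensus))
  h <- scan_contigs(contig, list(m), min_partial_codons = 0L,
                    min_hit_bits = 0)
  h <- h[h$score == max(h$score), ]
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 0)
  expect_equal(h$end, 3 * m$length)
  expect_equal(h$strand, "+")
  expect_equal(h$score, m$max_score, tolerance = 1e-9)
})

test_that("scanning is strand-symmetric up to coordinate reflection", {
  withr::with_seed(21, {
    m <- build_exon_models(toy_alignment("MKWVDEQRHL"))[[1]]
    pad <- paste0(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                  collapse = "")
    fwd <- c(k = paste0(pad, encode_peptide(m$consensus), pad))
    rev <- c(k = exonweaver:::revcomp(fwd[[1]]))
    hf <- scan_contigs(fwd, list(m), min_partial_codons = 0L)
    hr <- scan_contigs(rev, list(m), min_partial_codons = 0L)
    expect_equal(nrow(hf), nrow(hr))
    len <- nchar(fwd[[1]])
    expect_setequal(paste(len - hr$end, len - hr$start, hr$score),
                    paste(hf$start, hf$end, hf$score))
    expect_setequal(hf$score, hr$score)
  })
})

test_that("raising the threshold never adds hits", {
  withr::with_seed(22, {
    m <- build_exon_models(toy_alignment("MKWVDEQRHL"))[[1]]
    contig <- c(x = paste0(sample(c("A", "C", "G", "T"), 3000,
                                  replace = TRUE), collapse = ""))
    prev <- Inf
    for (thr in c(2, 5, 10, 20)) {
      n <- nrow(scan_contigs(contig, list(m), threshold = thr,
                             min_partial_codons = 0L, min_hit_bits = 0))
      expect_lte(n, prev)
      prev <- n
    }
  })
})

test_that("planted exons in random contigs are hit at the exact interval", {
  withr::with_seed(23, {
    aln <- toy_alignment("MKWVDEQRHLNCYF")
    m <- build_exon_models(aln)[[1]]
    found <- 0L
    for (i in 1:15) {
      off <- sample(100:2900, 1)
      bg <- paste0(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                   collapse = "")
      planted <- encode_peptide(m$consensus)
      contig <- c(z = paste0(substr(bg, 1, off), planted,
                             substr(bg, off + 1, nchar(bg))))
      h <- scan_contigs(contig, list(m), min_partial_codons = 0L)
      found <- found + any(h$start == off & h$end == off + nchar(planted))
    }
    expect_gte(found, 14)
  })
})

test_that("pseudogene windows with isolated stops survive, stop-rich ones die", {
  m <- build_exon_models(toy_alignment("MKWVDEQRHLNCYFAGHPKW"))[[1]]
  pep <- m$consensus
  one_stop <- paste0(substr(pep, 1, 9), "*", substr(pep, 11, 20))
  cds <- sub("...$", "TAA",
             encode_peptide(substr(one_stop, 1, 9)))
  cds <- paste0(encode_peptide(substr(pep, 1, 9)), "TAA",
                encode_peptide(substr(pep, 11, 20)))
  h <- scan_contigs(c(c1 = cds), list(m), min_partial_codons = 0L)
  expect_equal(nrow(h[h$partial == FALSE, ]), 1)
  many <- paste0(encode_peptide(substr(pep, 1, 5)),
                 strrep("TAA", 10),
                 encode_peptide(substr(pep, 16, 20)))
  h2 <- scan_contigs(c(c1 = many), list(m), threshold = 0,
                     min_partial_codons = 0L, min_hit_bits = 0)
  expect_false(any(h2$end - h2$start == 60 & !h2$partial))
})

test_that("boundary refinement snaps to planted splice sites", {
  withr::with_seed(31, {
    m <- build_exon_models(toy_alignment("MKWVDEQRHL"))[[1]]
    exon <- encode_peptide(m$consensus)
    up <- paste0(paste0(sample(c("A", "C"), 48, replace = TRUE),
                        collapse = ""), "AG")   # acceptor just before exon
    down <- paste0("GT", paste0(sample(c("A", "C"), 48, replace = TRUE),
                                collapse = ""))  # donor just after
    contig <- paste0(up, exon, down)
    hit <- data.frame(contig = "c1", start = 50L + 3L,
                      end = 50L + nchar(exon) + 3L, strand = "+",
                      frame = 0L, paralog = "P", exon = 1L, score = 10,
                      partial = FALSE)
    ref <- refine_splice_boundaries(hit, contig, window_nt = 12L)
    expect_equal(ref$start, 50L)
    expect_equal(ref$end, 50L + nchar(exon))
    # window 0 leaves the hit unchanged
    ref0 <- refine_splice_boundaries(hit, contig, window_nt = 0L)
    expect_equal(ref0$start, hit$start)
    # no GT/AG anywhere: unchanged
    bare <- strrep("C", 200)
    refn <- refine_splice_boundaries(hit, bare, window_nt = 12L)
    expect_equal(refn$start, hit$start)
    expect_equal(refn$end, hit$end)
  })
})
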