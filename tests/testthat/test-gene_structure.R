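# intronless toy gene with a backing sequence, exons at codon boundaries
toy_gene <- function(n_codons = 100L, seed = 9L) {
  withr::with_seed(seed, {
    cds <- exonweaver:::.rand_cds(n_codons)
    gene_model("toy", "fam",
               data.frame(contig = "gene", start = 0L,
                          end = 3L * n_codons, strand = "+",
                          exon_index = 1L),
               seq = cds)
  })
}

test_that("the intron coordinate closed form matches the a/b/c convention", {
  expect_equal(intron_label(255), "85c")   # after base 255 = 3 x 85
  expect_equal(intron_label(1), "1a")
  expect_equal(intron_label(2), "1b")
  expect_equal(intron_label(256), "86a")
})

test_that("planting and re-mapping an intron round-trips for every offset", {
  g <- toy_gene(100L)
  intron <- paste0("GT", strrep("ATCT", 20), "AG")
  for (n in 1:299) {
    g2 <- plant_intron_gain(g, n, intron)
    mapped <- map_intron_positions(g2)
    expect_equal(nrow(mapped), 1)
    expect_equal(mapped$label,
                 intron_label(n))
    expect_equal(mapped$cds_offset, n)
  }
})

test_that("intron insertion preserves the translation and shifts coordinates", {
  g <- toy_gene(100L)
  intron <- paste0("GT", strrep("TTCA", 30), "AG")
  g2 <- plant_intron_gain(g, 255L, intron)
  expect_equal(nrow(g2$exons), 2)
  expect_equal(g2$exons$end[1], 255)                    # between codons 85/86
  expect_equal(g2$exons$start[2], 255 + nchar(intron))  # shifted by intron
  expect_identical(exonweaver:::translate_dna(gene_cds(g2)),
                   exonweaver:::translate_dna(gene_cds(g)))
  g3 <- plant_intron_gain(g, 1L, intron)                # phase-a in codon 1
  expect_equal(map_intron_positions(g3)$label, "1a")
  expect_error(plant_intron_gain(g, 0L, intron), "strictly inside")
  expect_error(plant_intron_gain(g, 300L, intron), "strictly inside")
  expect_error(plant_intron_gain(g, 10L, "TTAA"), "begin GT")
  g4 <- plant_intron_gain(g, 30L, intron)
  expect_error(plant_intron_gain(g4, 30L, intron), "existing intron")
})

test_that("insertions relative to the reference shift the projected label", {
  # gene has a 2-residue insertion before the intron: own residue 87,
  # reference residue 85
  qrow <- strrep("M", 100)                               # 100 residues
  rrow <- paste0(strrep("M", 40), "--", strrep("M", 58)) # 98 residues
  g <- toy_gene(100L)
  intron <- paste0("GT", strrep("GGCA", 25), "AG")
  g2 <- plant_intron_gain(g, 261L, intron)              # own codon 87
  mapped <- map_intron_positions(g2, query_aln = qrow, ref_aln = rrow)
  expect_equal(mapped$own_residue, 87)
  expect_equal(mapped$reference_residue, 85)
  expect_equal(mapped$label, "85c")
})

test_that("introns projecting into reference gaps are unplaced, not forced", {
  g <- toy_gene(10L)
  intron <- paste0("GT", strrep("TAGC", 20), "AG")
  g2 <- plant_intron_gain(g, 15L, intron)               # codon 5
  qrow <- strrep("M", 10)
  rrow <- paste0("MMMM", "-", "MMMMM")                  # ref gapped at col 5
  mapped <- map_intron_positions(g2, query_aln = qrow, ref_aln = rrow)
  expect_true(mapped$unplaced)
  expect_true(is.na(mapped$label))
})

test_that("structure diffs report gains, losses and split exons", {
  ref <- c("30c", "60c", "85c")
  same <- data.frame(cds_offset = c(90, 180, 255), own_residue = c(30, 60, 85),
                     reference_residue = c(30, 60, 85),
                     phase = c("c", "c", "c"), label = ref, unplaced = FALSE)
  d0 <- diff_structure(same, ref)
  expect_length(d0$gained_introns, 0)
  expect_length(d0$lost_introns, 0)

  plus <- rbind(same, data.frame(cds_offset = 150, own_residue = 50,
                                 reference_residue = 50, phase = "c",
                                 label = "50c", unplaced = FALSE))
  d1 <- diff_structure(plus, ref)
  expect_identical(d1$gained_introns, "50c")
  expect_equal(d1$split_exons[[1]]$exon, 2)              # inside ref exon 2
  expect_identical(d1$split_exons[[1]]$parts, c("2.1", "2.2"))

  d2 <- diff_structure(same, ref, missing_exons = 15L)
  expect_identical(d2$lost_exons, 15L)

  # +-1 residue jitter merges as identical
  jitter <- same
  jitter$reference_residue[1] <- 31; jitter$label[1] <- "31c"
  expect_length(diff_structure(jitter, ref)$gained_introns, 0)
})

test_that("protosplice detection requires AG|GY and handles both strands", {
  seq <- paste0("AAACAG", strrep("GTXXAG", 1), "GTAAA")  # CAG | intron | GT..
  s <- paste0("AAACAG", "GTCCCCAG", "GTAAA")
  # intron occupies [6, 14): upstream exonic ..CAG, downstream GT
  r <- detect_protosplice(s, 6L, 14L)
  expect_true(r$is_protosplice)
  expect_equal(r$context, "AGGT")
  # lower case and reverse strand give the same call
  rc <- exonweaver:::revcomp(tolower(s))
  r2 <- detect_protosplice(rc, nchar(s) - 14L, nchar(s) - 6L, strand = "-")
  expect_true(r2$is_protosplice)
  # AAGC (the documented exception pattern) is not a protosplice site
  s3 <- paste0("AAAAAG", "GTCCCCAG", "CAAAA")
  expect_false(detect_protosplice(s3, 6L, 14L)$is_protosplice)
  # G followed by a purine fails the Y requirement
  s4 <- paste0("AAACAG", "GTCCCCAG", "GAAAA")
  expect_false(detect_protosplice(s4, 6L, 14L)$is_protosplice)
  # insufficient context is unknown, not false
  expect_true(is.na(detect_protosplice("AGGT", 0L, 2L)$is_protosplice))
  expect_true(is.na(is_protosplice_context(NA)))
  expect_true(is_protosplice_context("AGGC"))
  expect_false(is_protosplice_context("AGGA"))
})

test_that("gene copies are classified by exon count, stops and frameshifts", {
  # intronless clean ORF in a 16-exon family: retrogene
  retro <- toy_gene(50L)
  expect_equal(classify_gene_copy(retro, family_exon_count = 16L)$class,
               "retrogene")
  # intronless with frameshifts: pseudo-retrogene
  fs <- retro
  fs$seq <- substr(fs$seq, 1, 149)
  fs$exons$end <- 149L
  cl <- classify_gene_copy(fs, family_exon_count = 16L)
  expect_equal(cl$class, "pseudo-retrogene")
  expect_gte(cl$n_frameshifts, 1)
  # multi-exon with a premature stop: pseudogene
  g <- toy_gene(50L, seed = 12)
  g2 <- plant_intron_gain(g, 60L, paste0("GT", strrep("CA", 40), "AG"))
  bases <- strsplit(g2$seq, "")[[1]]
  bases[10:12] <- c("T", "A", "A")
  g2$seq <- paste0(bases, collapse = "")
  cl2 <- classify_gene_copy(g2, family_exon_count = 16L)
  expect_equal(cl2$class, "pseudogene")
  expect_gte(cl2$n_stops, 1)
  # multi-exon clean ORF: intact
  expect_equal(classify_gene_copy(g2e <- plant_intron_gain(
    toy_gene(50L, seed = 13), 60L,
    paste0("GT", strrep("CA", 40), "AG")), 16L)$class, "intact")
})

test_that("gaps explained by missing exon hits are not called introns", {
  # copy with exons 1,2,4 observed; exon 3 (60 nt) undetected inside a
  # contiguous coding stretch: gap 60 must not become an intron
  exp_len <- c(`1` = 90, `2` = 60, `3` = 60, `4` = 90)
  g <- gene_model("x", "fam",
                  data.frame(contig = "c", start = c(0L, 90L, 210L),
                             end = c(90L, 150L, 300L), strand = "+",
                             exon_index = c(1L, 2L, 4L)))
  ins <- recovered_introns(g, exp_len)
  expect_equal(nrow(ins), 0)
  # with a real 500 nt intron on top of the missing exon the residual calls
  g2 <- gene_model("y", "fam",
                   data.frame(contig = "c", start = c(0L, 90L, 710L),
                              end = c(90L, 150L, 800L), strand = "+",
                              exon_index = c(1L, 2L, 4L)))
  ins2 <- recovered_introns(g2, exp_len)
  expect_equal(nrow(ins2), 1)
  expect_equal(ins2$length, 500)
  expect_equal(ins2$cds_offset, 150 + 60)   # counts the missing exon
})

test_that("cross-contig introns are called from splice evidence", {
  left <- paste0(strrep("A", 90), "GT", strrep("C", 30))
  right <- paste0(strrep("T", 28), "AG", strrep("G", 90))
  contigs <- c(L = left, R = right)
  g <- gene_model("x", "fam",
                  data.frame(contig = c("L", "R"), start = c(0L, 30L),
                             end = c(90L, 120L), strand = "+",
                             exon_index = 1:2))
  ins <- recovered_introns(g, c(`1` = 90, `2` = 90), contigs = contigs)
  expect_equal(nrow(ins), 1)
  expect_true(ins$cross_contig)
  expect_equal(ins$cds_offset, 90)
  # without the GT donor no intron is claimed
  contigs2 <- contigs
  substr(contigs2["L"], 91, 92) <- "CC"
  ins2 <- recovered_introns(g, c(`1` = 90, `2` = 90), contigs = contigs2)
  expect_equal(nrow(ins2), 0)
})
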