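toy_genome <- function(contig) sequence_catalog(c(ctg = contig), "genome")

test_that("precursor extraction takes flanks, clips at contig ends, handles strands", {
  set.seed(61)
  left <- random_seq(200, c("A", "C", "G", "T"))
  read <- random_seq(22, c("A", "C", "G", "T"))
  right <- random_seq(200, c("A", "C", "G", "T"))
  g <- toy_genome(paste0(left, read, right))
  locus <- list(contig = "ctg", start = 200L, end = 222L, strand = "+")
  ## flank 0: the read itself
  p0 <- extract_precursor(g, locus, flank = 0)
  expect_equal(p0$precursor, read)
  expect_equal(p0$mature_offset, 0L)
  ## flank 75 mid-contig: 172 nt, offset 75
  p75 <- extract_precursor(g, locus, flank = 75)
  expect_equal(nchar(p75$precursor), 172L)
  expect_equal(p75$mature_offset, 75L)
  expect_equal(substr(p75$precursor, 76, 97), read)
  ## read 10 nt from the contig start: clipped to 10 + 22 + 75
  g2 <- toy_genome(paste0(substr(left, 1, 10), read, right))
  pc <- extract_precursor(g2, list(contig = "ctg", start = 10L, end = 32L,
                                   strand = "+"), flank = 75)
  expect_equal(nchar(pc$precursor), 10L + 22L + 75L)
  expect_equal(pc$mature_offset, 10L)
  ## minus strand: reverse complement, offset measured from the 3' flank
  pm <- extract_precursor(g, list(contig = "ctg", start = 200L, end = 222L,
                                  strand = "-"), flank = 30)
  expect_equal(substr(pm$precursor, 31, 52), revcomp(read))
  expect_equal(pm$mature_offset, 30L)
  ## bounds errors
  expect_error(extract_precursor(g, list(contig = "ctg", start = -1L,
                                         end = 22L, strand = "+")), "bounds")
  expect_error(extract_precursor(g, list(contig = "nope", start = 0L,
                                         end = 22L, strand = "+")), "contig")
})

test_that("hairpin classification enforces energy, topology and arm placement", {
  set.seed(62)
  arm <- random_seq(30, c("C", "G", "A", "T")[c(1, 1, 2, 2, 3, 4)])
  unit <- paste0(arm, random_seq(8, c("A", "C", "G", "T")), revcomp(arm))
  prec <- paste0(random_seq(40, c("A", "C", "G", "T")), unit,
                 random_seq(40, c("A", "C", "G", "T")))
  ## mature on the 5' arm
  cl5 <- classify_hairpin(prec, 40L, 22L)
  expect_true(cl5$pass)
  expect_equal(cl5$arm, "5p")
  ## mature on the 3' arm (the reverse-complement side of the stem)
  cl3 <- classify_hairpin(prec, 40L + 38L + 8L, 22L)
  expect_true(cl3$pass)
  expect_equal(cl3$arm, "3p")
  ## mature across the terminal loop fails
  cll <- classify_hairpin(prec, 40L + 20L, 30L)
  expect_false(cll$pass)
  expect_true(cll$reason %in% c("loop_overlap", "multi_loop"))
  ## energy gate: a weak hairpin fails with the energy reason
  weak <- paste0("GCGCAT", "TTTT", "ATGCGC")
  clw <- classify_hairpin(weak, 0L, 6L)
  expect_false(clw$pass)
  expect_equal(clw$reason, "energy")
  expect_gt(clw$mfe, -20)
  ## threshold is strict: same weak hairpin passes a permissive threshold
  expect_true(classify_hairpin(prec, 40L, 22L, mfe_threshold = -5)$pass)
  ## mature outside the precursor is a contract violation
  expect_error(classify_hairpin(prec, nchar(prec) + 5L, 22L), "outside")
})

test_that("topology rules reject multiloops and loop overlaps on explicit structures", {
  ## inject a fixed fold so the topology logic is tested in isolation
  stub <- function(db, mfe = -30) function(seq, par) list(structure = db,
                                                          mfe = mfe)
  ##      1234567890123456789012345678901234567890
  db2 <- "((((..((((....))))..((((....))))...))))"
  seqc <- strrep("A", nchar(db2))
  ## mature spanning both inner hairpins: two terminal loops in its stem
  cl <- classify_hairpin(seqc, 7L, 24L, fold_fun = stub(db2))
  expect_false(cl$pass)
  expect_equal(cl$reason, "multi_loop")
  ## mature confined to one inner hairpin arm: that stem has one loop
  cl5 <- classify_hairpin(seqc, 6L, 4L, fold_fun = stub(db2))
  expect_true(cl5$pass)
  expect_equal(cl5$arm, "5p")
  ## mature across a terminal loop is rejected
  db1 <- "....((((((((....))))))))...."
  clo <- classify_hairpin(strrep("A", nchar(db1)), 9L, 10L,
                          fold_fun = stub(db1))
  expect_false(clo$pass)
  expect_equal(clo$reason, "loop_overlap")
  ## entirely unpaired mature
  cln <- classify_hairpin(strrep("A", nchar(db1)), 0L, 3L,
                          fold_fun = stub(db1))
  expect_false(cln$pass)
  expect_equal(cln$reason, "no_stem")
})

test_that("novel naming is ordered, arm-suffixed, shared per precursor, and stable", {
  acc <- tibble::tibble(
    contig = c("c2", "c1", "c1"),
    start = c(50L, 10L, 10L), end = c(100L, 80L, 80L),
    strand = "+",
    mature = c("CCC", "AAA", "TTT"),
    arm = c("3p", "5p", "3p"))
  named <- name_novel(acc)
  expect_equal(named$name[named$mature == "AAA"], "ast-Novel-1-5p")
  expect_equal(named$name[named$mature == "TTT"], "ast-Novel-1-3p")
  expect_equal(named$name[named$mature == "CCC"], "ast-Novel-2-3p")
  expect_identical(name_novel(acc)$name, named$name)  # deterministic re-run
})

test_that("known-similarity screen uses edit distance with threshold 3", {
  known <- sequence_catalog(c(k1 = "TGAGATCACTTTGAAAGCTGAT"), "known_mirna")
  expect_equal(check_not_known("TGAGATCACTTTGAAAGCTGAT", known), "known-like")
  ## exactly distance 3: still known-like at the default threshold
  d3 <- "TGACATCACTTTGAAAGCTCAA"
  expect_equal(c(utils::adist("TGAGATCACTTTGAAAGCTGAT", d3)), 3)
  expect_equal(check_not_known(d3, known), "known-like")
  set.seed(64)
  far <- random_seq(22, c("A", "C", "G", "T"))
  expect_gt(min(utils::adist(far, known$seq)), 3)
  expect_equal(check_not_known(far, known), "novel")
})

test_that("discovery recovers planted loci and rejects known-like matures", {
  cfg <- simulation_config(read_depth = 5000, n_known_mirnas = 5,
                           n_novel_loci = 3)
  sim <- simulate_genome(cfg)
  reads <- tibble::tibble(seq = sim$novel_loci$mature, count = 10L)
  nov <- discover_novel(reads, sim$genome, sim$known)
  expect_equal(nrow(nov), 3)
  expect_setequal(nov$mature, sim$novel_loci$mature)
  expect_true(all(nov$arm == "5p"))
  expect_true(all(nov$mfe < -20))
  ## a mature identical to a known sequence is screened out
  reads2 <- tibble::tibble(seq = c(sim$novel_loci$mature[1], sim$known$seq[1]),
                           count = 10L)
  nov2 <- discover_novel(reads2, sim$genome, sim$known)
  expect_equal(nrow(nov2), 1)
  ## min_count gate
  expect_equal(nrow(discover_novel(dplyr::mutate(reads, count = 1L),
                                   sim$genome, sim$known, min_count = 2)), 0)
})
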