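make_known <- function() {
  t2 <- load_fixtures()$table2
  sequence_catalog(setNames(t2$sequence, t2$mirna), class = "known_mirna")
}

test_that("known-miRNA matching is zero-mismatch with bounded isomiR ends", {
  known <- make_known()
  ## the published mature sequence maps to its own name
  expect_equal(match_known_mirna("TGTGATGTGACGTAGTGGTAC", known),
               "ast-miR-989")
  ## one internal mismatch: no match anywhere
  expect_true(is.na(match_known_mirna("TGTGATGTGACTTAGTGGTAC", known)))
  ## 19-nt 5' prefix of a 22-nt mature matches as a substring
  mat <- known$seq[known$name == "ast-miR-184a"]
  expect_equal(match_known_mirna(substr(mat, 1, 19), known), "ast-miR-184a")
  ## read containing the mature with 3 extra bases total matches
  expect_equal(match_known_mirna(paste0("AC", mat, "G"), known),
               "ast-miR-184a")
  ## but 4 extra bases is beyond the isomiR tolerance
  expect_true(is.na(match_known_mirna(paste0("AC", mat, "GG"), known)))
  ## strict mode: identity only
  expect_true(is.na(match_known_mirna(substr(mat, 1, 19), known,
                                      max_flank = 0, substring = FALSE)))
})

test_that("mature deduplication merges identical sequences under the smallest name", {
  cat <- sequence_catalog(c(zzz = "ACGTACGTACGTACGTAC",
                            aaa = "ACGTACGTACGTACGTAC",
                            mmm = "GGGGTTTTCCCCAAAATT"), "known_mirna")
  dd <- dedupe_mature(cat)
  expect_equal(nrow(dd), 2)
  expect_true("aaa" %in% dd$name)
  expect_false("zzz" %in% dd$name)
  expect_equal(dedupe_mature(dd), dd)   # already unique: identity
  empty <- sequence_catalog(setNames(character(0), character(0)),
                            "known_mirna")
  expect_equal(nrow(dedupe_mature(empty)), 0)
})

test_that("hierarchical assignment honors catalog priority and partitions reads", {
  known <- sequence_catalog(c(m1 = "TGAGATCACTTTGAAAGCTGAT"), "known_mirna")
  genome <- sequence_catalog(
    c(ctg = paste0("CCCCC", "TGAGATCACTTTGAAAGCTGAT", "AATTGGCCAATTGGCCAA",
                   "GGGGG")), "genome")
  reads <- tibble::tibble(
    seq = c("TGAGATCACTTTGAAAGCTGAT",   # known AND genome -> known wins
            "AATTGGCCAATTGGCCAA",       # genome only
            "TTTTTTTTTTTTTTTTTT"),      # nothing
    count = c(5L, 2L, 1L))
  asg <- assign_reads(reads, list(genome, known))  # order input is irrelevant
  expect_equal(asg$assigned_class,
               c("known_mirna", "genome", "unassigned"))
  expect_equal(asg$feature_name, c("m1", "ctg", NA))
  ## each read in exactly one class; totals conserved
  expect_equal(sum(asg$count), sum(reads$count))
  ## order stability: permuting reads never changes the assignment
  perm <- sample(nrow(reads))
  asg2 <- assign_reads(reads[perm, ], list(genome, known))
  expect_equal(asg2$assigned_class, asg$assigned_class[perm])
})

test_that("genome matching searches both strands, other catalogs sense only", {
  genome <- sequence_catalog(c(ctg = "AAACCCGGGTTTACGTACGTAA"), "genome")
  read_rc <- revcomp("CCCGGGTTTACGTACG")
  expect_equal(match_substring(read_rc, genome, both_strands = TRUE), "ctg")
  ncrna <- sequence_catalog(c(rna1 = "AAACCCGGGTTTACGTACGTAA"), "ncrna")
  expect_true(is.na(match_substring(read_rc, ncrna)))
})

test_that("assignment agrees with a brute-force scan over all read/entry pairs", {
  set.seed(11)
  entries <- replicate(20, random_seq(40, c("A", "C", "G", "T")))
  known <- sequence_catalog(setNames(replicate(15, random_seq(22, c("A", "C", "G", "T"))),
                                     sprintf("k%02d", 1:15)), "known_mirna")
  ncrna <- sequence_catalog(setNames(entries[1:10], sprintf("n%02d", 1:10)),
                            "ncrna")
  genome <- sequence_catalog(setNames(entries[11:20], sprintf("g%02d", 11:20)),
                             "genome")
  ## reads: planted positives from each catalog + random negatives
  reads <- c(known$seq[1:5],
             substr(ncrna$seq[1:5], 5, 28),
             substr(genome$seq[1:5], 10, 31),
             revcomp(substr(genome$seq[6:8], 3, 24)),
             replicate(50, random_seq(22, c("A", "C", "G", "T"))))
  reads <- tibble::tibble(seq = unique(reads), count = 1L)
  asg <- assign_reads(reads, list(known, ncrna, genome), max_flank = 0,
                      substring = FALSE)
  ## oracle: first catalog (priority order) with a literal hit
  oracle <- vapply(reads$seq, function(r) {
    if (r %in% known$seq) return("known_mirna")
    if (any(vapply(ncrna$seq, function(e) grepl(r, e, fixed = TRUE),
                   logical(1)))) return("ncrna")
    hitg <- any(vapply(genome$seq, function(e) {
      grepl(r, e, fixed = TRUE) || grepl(r, revcomp(e), fixed = TRUE)
    }, logical(1)))
    if (hitg) return("genome")
    "unassigned"
  }, character(1), USE.NAMES = FALSE)
  expect_equal(asg$assigned_class, oracle)
})

test_that("feature counting sums collapsed counts and conserves the library total", {
  known <- sequence_catalog(c(m1 = "ACGTACGTACGTACGTACGTAC",
                              m2 = "TTTTCCCCGGGGAAAATTTTCC"), "known_mirna")
  reads <- tibble::tibble(seq = c("ACGTACGTACGTACGTACGTAC",
                                  substr("ACGTACGTACGTACGTACGTAC", 1, 20),
                                  "GGGGGGGGGGGGGGGGGGGG"),
                          count = c(3L, 2L, 7L))
  asg <- assign_reads(reads, list(known))
  ct <- count_features(asg, "AM")
  expect_equal(ct$count[ct$feature_name == "m1"], 5)
  expect_false("m2" %in% ct$feature_name)   # no reads -> no row (cell 0)
  unas <- sum(asg$count[asg$assigned_class == "unassigned"])
  expect_equal(sum(ct$count) + unas, sum(reads$count))
})
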