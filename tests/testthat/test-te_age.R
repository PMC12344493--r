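k2p_closed_form <- function(P, Q) -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))

test_that("kimura2p matches the closed form on constructed alignments", {
  ## identical sequences
  aln <- insertion_alignment("t", "f", "ACGTACGT", "ACGTACGT")
  r <- kimura2p(aln)
  expect_equal(c(r$P, r$Q, r$d), c(0, 0, 0))

  ## 1000 CpG-free columns: 100 transitions (A->G), 50 transversions
  cons <- paste(rep("A", 1000), collapse = "")
  ins <- strsplit(cons, "")[[1]]
  ins[1:100] <- "G"; ins[101:150] <- "C"
  aln2 <- insertion_alignment("t", "f", cons, paste(ins, collapse = ""))
  r2 <- kimura2p(aln2, cpg_modified = TRUE)
  expect_equal(r2$P, 0.1)
  expect_equal(r2$Q, 0.05)
  expect_equal(r2$d, k2p_closed_form(0.1, 0.05))

  ## grid of (P, Q) pairs, CpG-free consensus
  for (np in c(20, 60)) for (nq in c(10, 40)) {
    ins <- strsplit(cons, "")[[1]]
    ins[seq_len(np)] <- "G"
    ins[np + seq_len(nq)] <- "T"
    r3 <- kimura2p(insertion_alignment("t", "f", cons,
                                       paste(ins, collapse = "")))
    expect_equal(r3$d, k2p_closed_form(np / 1000, nq / 1000))
  }
})

test_that("CpG-modified weighting discounts consensus-CpG transitions", {
  ## only mismatch: C->T transition inside a consensus CpG
  cons <- "AACGTTAAGT"
  ins <- "AATGTTAAGT"
  r <- kimura2p(insertion_alignment("t", "f", cons, ins),
                cpg_modified = TRUE)
  expect_equal(r$P, 0.1 / 10)
  r0 <- kimura2p(insertion_alignment("t", "f", cons, ins),
                 cpg_modified = FALSE)
  expect_equal(r0$P, 1 / 10)
  expect_lt(r$d, r0$d)
  ## the G of the dyad is discounted too
  r2 <- kimura2p(insertion_alignment("t", "f", "ACGA", "ACAA"))
  expect_equal(r2$P, 0.1 / 4)
  ## cpg_weight = 0 drops CpG transitions entirely
  r3 <- kimura2p(insertion_alignment("t", "f", cons, ins),
                 cpg_weight = 0)
  expect_equal(r3$P, 0)
  ## no-op on CpG-free alignments
  consf <- paste(rep(c("A", "T"), 100), collapse = "")
  insf <- sub("^A", "G", consf)
  expect_equal(kimura2p(insertion_alignment("t", "f", consf, insf),
                        cpg_modified = TRUE)$d,
               kimura2p(insertion_alignment("t", "f", consf, insf),
                        cpg_modified = FALSE)$d)
})

test_that("gaps/N are excluded; saturation flags instead of erroring", {
  r <- kimura2p(insertion_alignment("t", "f", "AC-GTN", "ACCGTA"))
  expect_equal(r$n_compared, 4L)
  ## saturated: P + Q huge
  cons <- paste(rep("A", 10), collapse = "")
  ins <- paste(rep("G", 10), collapse = "")
  rs <- kimura2p(insertion_alignment("t", "f", cons, ins))
  expect_true(rs$saturated)
  expect_true(is.na(rs$d))
  expect_error(kimura2p(insertion_alignment("t", "f", "---", "AAA")),
               "comparable")
})

test_that("d is monotone in P at fixed Q over the defined domain", {
  ds <- vapply(seq(10, 300, by = 10), function(np) {
    cons <- paste(rep("A", 1000), collapse = "")
    ins <- strsplit(cons, "")[[1]]
    ins[seq_len(np)] <- "G"; ins[900:949] <- "C"
    kimura2p(insertion_alignment("t", "f", cons,
                                 paste(ins, collapse = "")))$d
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("distance is recovered from sequences evolved under K2P", {
  set.seed(41)
  cons <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  for (d_true in c(0.05, 0.15, 0.3)) {
    ins <- evolve_k2p(cons, d_true, kappa = 4)
    r <- kimura2p(insertion_alignment("t", "f", cons, ins),
                  cpg_modified = FALSE)
    expect_lt(abs(r$d - d_true) / d_true, 0.10)
  }
})

test_that("alignment reader round-trips and validates", {
  tf <- tempfile()
  writeLines(c(">te1\tLINE", "ACGT", "ACGA", "", ">te2\tLTR",
               "AAAA", "AAAG"), tf)
  alns <- read_insertion_alignments(tf)
  expect_length(alns, 2)
  expect_equal(alns[[1]]$te_id, "te1")
  expect_equal(alns[[2]]$family, "LTR")
  writeLines(c(">te1\tLINE", "ACGT"), tf)
  expect_error(read_insertion_alignments(tf), "malformed")
  expect_error(insertion_alignment("x", "f", "ACG", "AC"), "equal length")
  expect_error(insertion_alignment("x", "f", "AXG", "ACG"), "alphabet")
})

test_that("age_methylation_profile pools by family and bin", {
  k2p <- data.table::data.table(
    te_id = c("a", "b", "d", "e"), family = "fam",
    P = 0.01, Q = 0.01, d = c(0.02, 0.03, 0.25, NA),
    n_compared = 100L, saturated = c(FALSE, FALSE, FALSE, TRUE))
  sm <- data.table::data.table(
    feature_id = c("a", "b", "d", "e"), class_label = "fam",
    n_meth_reads = c(80, 60, 10, 5), n_total_reads = c(100, 100, 100, 100))
  prof <- age_methylation_profile(k2p, sm, age_bins = c(0, 0.1, 0.3))
  young <- prof[prof$age_bin == "[0,0.1)", ]
  expect_equal(young$n_insertions, 2L)
  expect_equal(young$level, 140 / 200)
  expect_equal(prof[prof$age_bin == "[0.1,0.3)", ]$level, 0.1)
  expect_equal(prof[prof$age_bin == "saturated", ]$level, 0.05)
  ## all insertions in one bin equals the family pool
  prof1 <- age_methylation_profile(k2p[1:2], sm[1:2],
                                   age_bins = c(0, 1))
  expect_equal(prof1$level, 140 / 200)
  expect_equal(nrow(prof1), 1L)
})
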