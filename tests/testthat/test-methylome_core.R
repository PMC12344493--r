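test_that("classify_context follows the CG/CHG/CHH definitions", {
  g <- c(chr = "ACGT")
  expect_equal(classify_context(g, "chr", 1, "+"),
               list(dinuc = "CG", trinuc = "CG"))
  g2 <- c(chr = "ACAGT")
  expect_equal(classify_context(g2, "chr", 1, "+"),
               list(dinuc = "CA", trinuc = "CHG"))
  ## final base: both windows run off the contig
  g3 <- c(chr = "AAC")
  expect_equal(classify_context(g3, "chr", 2, "+"),
               list(dinuc = NA_character_, trinuc = NA_character_))
  ## minus strand reads the reverse complement
  expect_equal(classify_context(c(chr = "ACGT"), "chr", 2, "-"),
               list(dinuc = "CG", trinuc = "CG"))
  expect_equal(classify_context(c(chr = "TACGG"), "chr", 4, "-"),
               list(dinuc = "CC", trinuc = "CHG"))
  expect_error(classify_context(g, "chr", 0, "+"), "not C")
  ## ambiguous base in the window
  expect_equal(classify_context(c(chr = "ACNT"), "chr", 1, "+"),
               list(dinuc = NA_character_, trinuc = NA_character_))
})

test_that("weighted_level pools read counts, not site fractions", {
  s <- sites_of("c", c(0, 5), n_meth = c(5, 5), n_total = c(10, 10))
  expect_equal(weighted_level(s)$level, 0.5)
  s <- sites_of("c", c(0, 5), n_meth = c(3, 0), n_total = c(4, 4))
  wl <- weighted_level(s)
  expect_equal(wl$level, 0.375)
  expect_equal(wl$n_sites, 2L)
  ## min_cov excludes sites, undefined result is flagged not zero
  expect_equal(weighted_level(s, min_cov = 5)$defined, FALSE)
  expect_true(is.na(weighted_level(s, min_cov = 5)$level))
})

test_that("weighted_level: order invariance and partition identity", {
  set.seed(1)
  tot <- rpois(500, 10) + 1L
  s <- sites_of("c", sample.int(1e5, 500), n_meth = rbinom(500, tot, .4),
                n_total = tot)
  w0 <- weighted_level(s)
  w1 <- weighted_level(s[sample(nrow(s)), ])
  expect_identical(w0$level, w1$level)
  ## conservation: pooled counts of a disjoint partition == whole
  grp <- sample(3, nrow(s), TRUE)
  parts <- lapply(1:3, function(g) weighted_level(s[grp == g, ]))
  m <- sum(vapply(parts, `[[`, 0, "n_meth_reads"))
  t <- sum(vapply(parts, `[[`, 0, "n_total_reads"))
  expect_identical(m / t, w0$level)
})

test_that("weighted_level recovers a simulated truth within 3 SE", {
  set.seed(11)
  n <- 10000
  tot <- rpois(n, 30) + 1L
  s <- sites_of("c", seq_len(n), n_meth = rbinom(n, tot, 0.32),
                n_total = tot)
  wl <- weighted_level(s)
  se <- sqrt(0.32 * 0.68 / sum(tot))
  expect_lt(abs(wl$level - 0.32), 3 * se)
})

test_that("global_context_levels separates contexts and spike-ins", {
  set.seed(2)
  n <- 4000
  tri <- sample(c("CG", "CHG", "CHH"), n, TRUE)
  di <- ifelse(tri == "CG", "CG", sample(c("CA", "CC", "CT"), n, TRUE))
  p <- ifelse(tri == "CG", 0.30, 0.003)
  tot <- rpois(n, 30) + 1L
  s <- methyl_sites(chrom = "chr1", pos = seq_len(n), strand = "+",
                    dinuc = di, trinuc = tri,
                    n_meth = rbinom(n, tot, p), n_total = tot)
  gl <- global_context_levels(s)
  cg <- gl[gl$context == "CG", ]
  expect_lt(abs(cg$level - 0.30),
            3 * sqrt(0.3 * 0.7 / cg$n_total_reads))
  for (ctx in c("CHG", "CHH", "dinuc_CA", "dinuc_CC", "dinuc_CT")) {
    row <- gl[gl$context == ctx, ]
    expect_lt(abs(row$level - 0.003),
              3 * sqrt(0.003 * 0.997 / row$n_total_reads))
  }
  ## excluded contigs drop out
  s2 <- rbind(s, sites_of("lambda", 1:10, n_meth = 10, n_total = 10,
                          trinuc = "CG", dinuc = "CG"))
  gl2 <- global_context_levels(s2, exclude_contigs = "lambda")
  expect_equal(gl2$n_sites, gl$n_sites)
  ## all-zero counts: defined level 0 with zero methylated reads
  s0 <- sites_of("c", 1:50, n_meth = 0, n_total = 5,
                 dinuc = "CA", trinuc = "CHH")
  gl0 <- global_context_levels(s0)
  expect_equal(gl0[gl0$context == "CX", ]$level, 0)
  expect_equal(gl0[gl0$context == "CX", ]$n_meth_reads, 0)
})

test_that("spike_in_qc contracts: missing contig, perfect controls", {
  s <- rbind(
    sites_of("lambda", 1:100, n_meth = 0, n_total = 10,
             dinuc = "CA", trinuc = "CHH"),
    sites_of("pUC19", 1:50, n_meth = 10, n_total = 10,
             dinuc = "CG", trinuc = "CG"))
  qc <- spike_in_qc(s)
  expect_equal(qc$nonconversion_rate, 0)
  expect_equal(qc$false_negative_rate, 0)
  expect_error(spike_in_qc(s, unmethylated_contig = "missing"),
               "missing")
})

test_that("dyad symmetry: mirrored r = 1, independent r ~ 0, contracts", {
  ## identical plus/minus levels across dyads (non-constant)
  lv <- c(2, 4, 6, 8)
  s <- rbind(
    sites_of("c", c(10, 20, 30, 40), "+", n_meth = lv, n_total = 10,
             trinuc = "CG", dinuc = "CG"),
    sites_of("c", c(11, 21, 31, 41), "-", n_meth = lv, n_total = 10,
             trinuc = "CG", dinuc = "CG"))
  expect_equal(dyad_symmetry(s, min_cov = 1)$r, 1)

  set.seed(3)
  n <- 10000
  s2 <- rbind(
    sites_of("c", seq(1, by = 10, length.out = n), "+",
             n_meth = round(runif(n) * 20), n_total = 20,
             trinuc = "CG", dinuc = "CG"),
    sites_of("c", seq(2, by = 10, length.out = n), "-",
             n_meth = round(runif(n) * 20), n_total = 20,
             trinuc = "CG", dinuc = "CG"))
  ds <- dyad_symmetry(s2, min_cov = 5)
  expect_equal(ds$n_dyads, n)
  expect_lt(abs(ds$r), 0.05)

  expect_error(dyad_symmetry(s[c(1, 5), ], min_cov = 1), "fewer than 2")
})

test_that("metaprofile matches a brute-force oracle on a toy set", {
  set.seed(4)
  feats <- features(chrom = c("c1", "c1", "c2"),
                    start = c(100, 400, 50), end = c(200, 520, 350),
                    strand = c("+", "-", "+"), id = c("a", "b", "d"))
  pos <- sort(sample.int(700, 150))
  tot <- rpois(150, 8) + 1L
  s <- sites_of(sample(c("c1", "c2"), 150, TRUE), pos,
                n_meth = rbinom(150, tot, runif(150)), n_total = tot)
  mp <- metaprofile(s, feats, body_bins = 5, flank_bp = 60,
                    flank_bins = 3, context_mode = "CX")
  oracle <- oracle_metaprofile(as.data.frame(s), as.data.frame(feats),
                               body_bins = 5, flank_bp = 60,
                               flank_bins = 3)
  expect_equal(mp$level, oracle)
})

test_that("metaprofile: uniform input, outside-only input, strand flip", {
  feats <- features("c", 100, 300, "+", id = "g")
  pos <- seq(0, 499)
  s <- sites_of("c", pos, n_meth = 4, n_total = 10)
  mp <- metaprofile(s, feats, body_bins = 4, flank_bp = 100,
                    flank_bins = 2, context_mode = "CX")
  expect_true(all(mp$level == 0.4))

  ## methylation only outside the feature
  s2 <- sites_of("c", pos, n_meth = ifelse(pos >= 100 & pos < 300, 0, 8),
                 n_total = 10)
  mp2 <- metaprofile(s2, feats, body_bins = 4, flank_bp = 100,
                     flank_bins = 2, context_mode = "CX")
  expect_true(all(mp2$level[mp2$zone == "body"] == 0))
  expect_true(all(mp2$level[mp2$zone != "body"] > 0))

  ## flipping all strands reverses the profile
  set.seed(5)
  tot <- rpois(500, 6) + 1L
  s3 <- sites_of("c", pos, n_meth = rbinom(500, tot, runif(500)),
                 n_total = tot)
  fplus <- features("c", 120, 340, "+", id = "g")
  fminus <- features("c", 120, 340, "-", id = "g")
  a <- metaprofile(s3, fplus, 6, 80, 3, "CX")
  b <- metaprofile(s3, fminus, 6, 80, 3, "CX")
  expect_equal(b$level, rev(a$level))
})
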