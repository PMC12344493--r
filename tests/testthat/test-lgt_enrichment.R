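mk_hits <- function(gene_id, sk, genus = NULL) {
  n <- length(sk)
  data.table::data.table(
    gene_id = gene_id, superkingdom = sk,
    genus = if (is.null(genus)) paste0("g", seq_len(n)) else genus,
    lineage = paste0(sk, ";x;", paste0("g", seq_len(n))),
    bitscore = seq(500, by = -1, length.out = n), evalue = 1e-10)
}

test_that("assign_categories implements the highest-level rules", {
  h <- rbind(mk_hits("v", rep("Viruses", 10)),
             mk_hits("ev", rep(c("Eukaryota", "Viruses"), each = 5)),
             mk_hits("e", rep("Eukaryota", 10)),
             mk_hits("m", rep(c("Eukaryota", "Bacteria", "Viruses"),
                              c(4, 3, 3))),
             mk_hits("p", c(rep("Bacteria", 6), rep("Archaea", 4))),
             mk_hits("ep", c(rep("Eukaryota", 8), rep("Bacteria", 2))))
  calls <- assign_categories(h, genes = c("v", "ev", "e", "m", "p",
                                          "ep", "none"))
  cat <- setNames(calls$category, calls$gene_id)
  expect_equal(unname(cat[c("v", "ev", "e", "m", "p", "ep", "none")]),
               c("Virus", "Eukaryote+Virus", "Eukaryote", "Mixed",
                 "Prokaryote", "Eukaryote+Prokaryote", "Unassigned"))
  expect_equal(calls$viral_fraction[calls$gene_id == "ev"], 0.5)
  expect_equal(calls$n_hits[calls$gene_id == "none"], 0L)
  ## permutation invariance in hit order
  set.seed(51)
  h2 <- h[sample(nrow(h)), ]
  calls2 <- assign_categories(h2, genes = calls$gene_id)
  expect_equal(calls2, calls)
})

test_that("two-sided Fisher p equals the enumeration oracle", {
  fp2 <- methylgate:::fisher_p2
  expect_equal(fp2(8, 2, 2, 8), oracle_fisher(8, 2, 2, 8),
               tolerance = 1e-12)
  expect_equal(fp2(5, 5, 5, 5), 1)
  expect_equal(fp2(0, 0, 10, 10), 1)          # zero margin
  ## random tables
  set.seed(52)
  for (i in 1:200) {
    tab <- as.integer(rmultinom(1, sample(4:80, 1), runif(4)))
    p <- fp2(tab[1], tab[2], tab[3], tab[4])
    po <- oracle_fisher(tab[1], tab[2], tab[3], tab[4])
    expect_lt(abs(p - po) / po, 1e-10)
  }
})

test_that("enrichment_test builds the table and flags correctly", {
  calls <- data.table::data.table(
    gene_id = sprintf("g%02d", 1:40),
    category = rep(c("Virus", "Eukaryote"), c(10, 30)),
    n_hits = 10L, viral_fraction = rep(c(1, 0), c(10, 30)))
  statuses <- data.table::data.table(
    feature_id = sprintf("g%02d", 1:40),
    status = c(rep("methylated", 9), "unmethylated",     # 9/10 viral meth
               rep("unmethylated", 28), "methylated", "undetermined"))
  r <- enrichment_test(calls, statuses, "Virus")
  expect_equal(unname(r$counts), c(9, 1, 1, 28))
  expect_equal(r$p_two_sided, oracle_fisher(9, 1, 1, 28),
               tolerance = 1e-12)
  expect_true(r$significant)
  expect_false(r$haldane)
  ## undetermined gene was excluded
  expect_equal(sum(r$counts), 39)
  ## sample OR
  expect_equal(r$odds_ratio, 9 * 28 / (1 * 1))
  ## zero cell triggers Haldane; (5,5/5,5) gives OR 1, p 1
  st2 <- data.table::data.table(
    feature_id = sprintf("g%02d", 1:40),
    status = rep(c("methylated", "unmethylated"), 20))
  r2 <- enrichment_test(calls, st2, "Virus")
  expect_false(r2$significant)
})

test_that("viral neighborhoods: examples, oracle, invariances", {
  mkgenes <- function(n, chrom = "c") {
    features(chrom, st <- seq(0, by = 1000, length.out = n), st + 800,
             "+", id = sprintf("%s_g%03d", chrom, 1:n))
  }
  g <- mkgenes(10)
  calls3 <- data.table::data.table(
    gene_id = g$id, category = "Eukaryote", n_hits = 10L,
    viral_fraction = 0)
  calls3[2:4, category := "Virus"]
  nb <- detect_viral_neighborhoods(g, calls3, min_genes = 2)
  expect_equal(nrow(nb), 1L)
  expect_equal(nb$n_viral, 3L)
  expect_equal(nb$start, g$start[2])
  expect_equal(nb$end, g$end[4])
  ## a single isolated viral gene is not a neighborhood
  calls4 <- data.table::copy(calls3)[, category := "Eukaryote"]
  calls4[5, category := "Virus"]
  expect_equal(nrow(detect_viral_neighborhoods(g, calls4,
                                               min_genes = 2)), 0L)

  ## planted 20-gene cluster with 2 interspersed host genes
  g2 <- mkgenes(60)
  vidx <- setdiff(11:32, c(18, 25))            # 20 viral, 2 host inside
  calls5 <- data.table::data.table(
    gene_id = g2$id, category = "Eukaryote", n_hits = 10L,
    viral_fraction = 0)
  calls5[vidx, category := "Virus"]
  nb2 <- detect_viral_neighborhoods(g2, calls5, max_gap_genes = 3,
                                    max_gap_bp = 20000, min_genes = 3)
  expect_equal(nrow(nb2), 1L)
  expect_equal(nb2$n_viral, 20L)
  expect_equal(nb2$start, g2$start[11])
  expect_equal(nb2$end, g2$end[32])
  expect_equal(nb2$n_total, 22L)

  ## equivalence with the naive chaining oracle on random layouts
  set.seed(53)
  for (i in 1:20) {
    gg <- rbind(mkgenes(40, "c1"), mkgenes(30, "c2"))
    vids <- sample(gg$id, 15)
    cc <- data.table::data.table(gene_id = gg$id,
                                 category = "Eukaryote",
                                 n_hits = 10L, viral_fraction = 0)
    cc[gg$id %in% vids, category := "Virus"]
    mg <- sample(0:4, 1); mb <- sample(c(3000, 8000, 50000), 1)
    nbx <- detect_viral_neighborhoods(gg, cc, max_gap_genes = mg,
                                      max_gap_bp = mb, min_genes = 2)
    ora <- oracle_chains(as.data.frame(gg), vids, mg, mb, 2)
    expect_equal(nrow(nbx), nrow(ora))
    if (nrow(ora)) {
      expect_equal(nbx$start, ora$start)
      expect_equal(nbx$end, ora$end)
      expect_equal(nbx$n_viral, ora$n_viral)
    }
    ## invariants
    expect_true(all(nbx$n_viral >= 2))
    if (nrow(nbx) > 1) {
      bychrom <- split(nbx, nbx$chrom)
      for (bb in bychrom)
        if (nrow(bb) > 1)
          expect_true(all(bb$start[-1] > bb$end[-nrow(bb)]))
    }
  }
})

test_that("dominant taxon is the modal viral genus of member hits", {
  g <- features("c", c(0, 1000, 2000), c(800, 1800, 2800), "+",
                id = c("a", "b", "d"))
  calls <- data.table::data.table(gene_id = c("a", "b", "d"),
                                  category = "Virus", n_hits = 10L,
                                  viral_fraction = 1)
  hits <- rbind(mk_hits("a", rep("Viruses", 3), rep("MimiX", 3)),
                mk_hits("b", rep("Viruses", 3), rep("MimiX", 3)),
                mk_hits("d", rep("Viruses", 3), rep("PhycoY", 3)))
  nb <- detect_viral_neighborhoods(g, calls, min_genes = 2, hits = hits)
  expect_equal(nb$dominant_taxon, "MimiX")
})
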