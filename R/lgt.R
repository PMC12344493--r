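#' Assign per-gene taxonomic-origin categories
#'
#' The superkingdom labels of a gene's retained hits are tallied into
#' three domains — Eukaryote (Eukaryota), Prokaryote (Bacteria +
#' Archaea) and Virus (Viruses). A domain is *represented* when its
#' share of the hits is at least `majority_rule` (default 0.2, the
#' operationalisation of "combinations" of highest-level categories).
#' One represented domain gives a pure category; two give a named
#' combination (Eukaryote+Prokaryote, Eukaryote+Virus,
#' Prokaryote+Virus); three give Mixed. Genes with zero retained hits
#' (e.g. only within-genus matches, all discarded) are Unassigned.
#'
#' @param hits hit table from [read_hit_table()] (already self-genus
#'   filtered and capped).
#' @param genes optional character vector of all gene ids; genes absent
#'   from `hits` are reported as Unassigned.
#' @param majority_rule minimum hit share for a domain to count.
#' @return `data.table`: gene_id, category, n_hits, viral_fraction.
#' @export
assign_categories <- function(hits, genes = NULL, majority_rule = 0.2) {
  h <- as.data.table(hits)
  h[, domain := fcase(superkingdom == "Eukaryota", "Eukaryote",
                      superkingdom %in% c("Bacteria", "Archaea"),
                      "Prokaryote",
                      superkingdom == "Viruses", "Virus")]
  per <- h[, {
    n <- .N
    sh <- c(Eukaryote = sum(domain == "Eukaryote") / n,
            Prokaryote = sum(domain == "Prokaryote") / n,
            Virus = sum(domain == "Virus") / n)
    rep_dom <- names(sh)[sh >= majority_rule]
    cat <- if (length(rep_dom) == 3L) "Mixed"
           else paste(rep_dom, collapse = "+")
    .(category = cat, n_hits = n, viral_fraction = sh[["Virus"]])
  }, by = gene_id]
  if (!is.null(genes)) {
    missing <- setdiff(genes, per$gene_id)
    if (length(missing))
      per <- rbind(per, data.table(gene_id = missing,
                                   category = "Unassigned",
                                   n_hits = 0L, viral_fraction = 0))
  }
  setorder(per, gene_id)
  per[]
}

## two-sided Fisher exact p for a 2x2 table (a b / c d): sum of
## hypergeometric point probabilities <= observed (with a 1e-7 relative
## slack against floating-point ties)
fisher_p2 <- function(a, b, c, d) {
  n <- a + b + c + d; r <- a + b; cc <- a + c
  if (r == 0L || cc == 0L || r == n || cc == n) return(1)
  klo <- max(0L, r + cc - n); khi <- min(r, cc)
  dh <- dhyper(klo:khi, cc, n - cc, r)
  obs <- dh[a - klo + 1L]
  min(1, sum(dh[dh <= obs * (1 + 1e-7)]))
}

#' Enrichment of a taxonomic category in the methylated fraction
#'
#' Two-sided Fisher exact test on the 2x2 table of methylation status
#' by category membership, over genes that are both classified
#' (methylated or unmethylated — undetermined excluded) and assigned
#' (Unassigned excluded). The sample odds ratio gets a Haldane 0.5
#' correction only when a zero cell exists (flagged); a zero margin
#' yields p = 1 and an undefined odds ratio.
#'
#' @param calls [assign_categories()] output.
#' @param statuses [classify_features()] output (feature_id, status).
#' @param category category to test.
#' @param alpha significance level (default 0.001, two-sided).
#' @return object of class `enrichment_result`.
#' @export
enrichment_test <- function(calls, statuses, category, alpha = 0.001) {
  tab <- enrichment_counts(calls, statuses, category)
  p <- fisher_p2(tab[1], tab[2], tab[3], tab[4])
  zero_margin <- (tab[1] + tab[2]) == 0 || (tab[3] + tab[4]) == 0 ||
    (tab[1] + tab[3]) == 0 || (tab[2] + tab[4]) == 0
  haldane <- !zero_margin && any(tab == 0)
  or <- if (zero_margin) NA_real_
        else if (haldane)
          (tab[1] + 0.5) * (tab[4] + 0.5) /
            ((tab[2] + 0.5) * (tab[3] + 0.5))
        else tab[1] * tab[4] / (tab[2] * tab[3])
  structure(list(category = category,
                 counts = setNames(tab, c("meth_cat", "meth_other",
                                          "unmeth_cat", "unmeth_other")),
                 odds_ratio = or, p_two_sided = p,
                 significant = p < alpha, alpha = alpha,
                 haldane = haldane, zero_margin = zero_margin),
            class = "enrichment_result")
}

enrichment_counts <- function(calls, statuses, cat_label) {
  st <- as.data.table(statuses)[, .(gene_id = feature_id, status)]
  x <- merge(as.data.table(calls), st, by = "gene_id")
  x <- x[x$status %in% c("methylated", "unmethylated") &
           x$category != "Unassigned"]
  m <- x$status == "methylated"; incat <- x$category == cat_label
  c(sum(m & incat), sum(m & !incat), sum(!m & incat), sum(!m & !incat))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Fisher exact (%s): OR = %s, p = %.3g %s(alpha = %g)\n  table: %s\n",
    x$category,
    if (is.na(x$odds_ratio)) "NA" else sprintf("%.3f", x$odds_ratio),
    x$p_two_sided, if (x$significant) "* " else "", x$alpha,
    paste(x$counts, collapse = " / ")))
  invisible(x)
}

#' Test every category at once
#'
#' @param calls,statuses,alpha as in [enrichment_test()].
#' @param bonferroni divide alpha by the number of categories tested.
#' @return `data.table` with one row per category (Unassigned never
#'   tested).
#' @export
enrichment_tests <- function(calls, statuses, alpha = 0.001,
                             bonferroni = FALSE) {
  cats <- setdiff(unique(calls$category), "Unassigned")
  a <- if (bonferroni) alpha / length(cats) else alpha
  rbindlist(lapply(sort(cats), function(ct) {
    r <- enrichment_test(calls, statuses, ct, a)
    data.table(category = ct, meth_cat = r$counts[1],
               meth_other = r$counts[2], unmeth_cat = r$counts[3],
               unmeth_other = r$counts[4], odds_ratio = r$odds_ratio,
               p_two_sided = r$p_two_sided, significant = r$significant)
  }))
}

#' Detect clustered viral-gene neighborhoods (endogenized-virus candidates)
#'
#' Genes called Virus (or a Virus-containing combination) are chained
#' greedily along each chromosome: the chain extends while the next
#' viral gene is separated by at most `max_gap_genes` intervening
#' non-viral genes *and* at most `max_gap_bp`. Chains with at least
#' `min_genes` viral members are emitted; the region spans the
#' outermost members and reports every gene inside.
#'
#' @param gene_features feature table of genes.
#' @param calls [assign_categories()] output.
#' @param max_gap_genes,max_gap_bp,min_genes chaining parameters
#'   (defaults 3 genes, 20 kb, 3 viral members).
#' @param hits optional hit table; when given, each neighborhood gets a
#'   `dominant_taxon` — the modal finest-rank (genus) label among the
#'   viral hits of its member genes.
#' @param viral_categories categories counted as viral.
#' @return `data.table`: id, chrom, start, end, n_viral, n_total,
#'   dominant_taxon, genes (comma-separated ids), viral_genes.
#' @export
detect_viral_neighborhoods <- function(gene_features, calls,
                                       max_gap_genes = 3L,
                                       max_gap_bp = 20000L,
                                       min_genes = 3L, hits = NULL,
                                       viral_categories = c(
                                         "Virus", "Eukaryote+Virus",
                                         "Prokaryote+Virus")) {
  g <- merge(as.data.table(gene_features),
             as.data.table(calls)[, .(id = gene_id, category)],
             by = "id", all.x = TRUE)
  g[is.na(category), category := "Unassigned"]
  g[, viral := category %in% viral_categories]
  setorderv(g, c("chrom", "start"))
  g[, rank := seq_len(.N), by = chrom]
  v <- g[viral == TRUE]
  if (nrow(v) == 0L)
    return(data.table(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_viral = integer(), n_total = integer(),
                      dominant_taxon = character(), genes = character(),
                      viral_genes = character()))
  ## chain: break when gene gap or bp gap exceeded
  v[, chain := cumsum(c(1L, ifelse(
    chrom[-1] == chrom[-.N] &
      (rank[-1] - rank[-.N] - 1L) <= max_gap_genes &
      (start[-1] - end[-.N]) <= max_gap_bp, 0L, 1L)))]
  chains <- v[, .(chrom = chrom[1], start = min(start), end = max(end),
                  n_viral = .N,
                  viral_genes = paste(id, collapse = ",")),
              by = chain][n_viral >= min_genes]
  if (nrow(chains) == 0L)
    return(data.table(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_viral = integer(), n_total = integer(),
                      dominant_taxon = character(), genes = character(),
                      viral_genes = character()))
  res <- lapply(seq_len(nrow(chains)), function(i) {
    ch <- chains[i]
    members <- g[chrom == ch$chrom & start < ch$end & end > ch$start]
    vids <- strsplit(ch$viral_genes, ",", fixed = TRUE)[[1]]
    dom <- NA_character_
    if (!is.null(hits)) {
      vh <- as.data.table(hits)[gene_id %in% vids &
                                  superkingdom == "Viruses"]
      if (nrow(vh)) {
        tb <- sort(table(vh$genus), decreasing = TRUE)
        dom <- names(tb)[1]
      }
    }
    data.table(chrom = ch$chrom, start = ch$start, end = ch$end,
               n_viral = ch$n_viral, n_total = nrow(members),
               dominant_taxon = dom,
               genes = paste(members$id, collapse = ","),
               viral_genes = ch$viral_genes)
  })
  out <- rbindlist(res)
  setorderv(out, c("chrom", "start"))
  out[, id := paste0("geve_", seq_len(.N))]
  setcolorder(out, c("id", "chrom", "start", "end", "n_viral",
                     "n_total", "dominant_taxon", "genes",
                     "viral_genes"))
  out[]
}
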