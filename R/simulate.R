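#' Specification of a synthetic methylome
#'
#' The defaults describe the statistical world the package is tested
#' against: a few-Mb genome carrying mostly unmethylated genes plus a
#' small hypermethylated fraction (bimodal gene-body levels), TE
#' families whose younger insertions are more methylated, a few
#' clusters of contiguous virus-derived genes that are themselves
#' hypermethylated, and the two spike-in controls (an unmethylated
#' lambda-like contig read at the non-conversion floor, and a
#' pUC19-like plasmid with near-complete CpG methylation). Per-site
#' read counts are binomial draws at Poisson coverage. See the methods
#' vignette for the rationale behind each default.
#'
#' @param seed integer; fixes every output byte. Internally fanned out
#'   to per-phase substreams (placement, truth, genome, counts, hits)
#'   so components are independently reproducible.
#' @param n_chroms,chrom_length,gc_content genome shape.
#' @param n_genes number of genes.
#' @param gene_length_meanlog,gene_length_sdlog,gene_length_range
#'   lognormal gene-length distribution, clipped.
#' @param intergenic_mean mean intergenic gap (bp, exponential + 20).
#' @param methylated_gene_fraction fraction of non-viral genes drawn
#'   methylated.
#' @param meth_beta shape parameters of the Beta distribution of true
#'   per-feature methylation levels of methylated features.
#' @param site_jitter half-width of the uniform per-site jitter around
#'   the feature-level truth.
#' @param context_mode context carrying the methylation signal.
#' @param nonconversion background apparent methylation (epsilon).
#' @param depth_mean mean sequencing depth (Poisson).
#' @param n_te_families,te_insertions_per_family,te_length_range TE
#'   content.
#' @param te_age_range range of per-family divergence (substitutions
#'   per site); insertions jitter around their family's value.
#' @param te_ts_tv transition/transversion ratio of TE mutations.
#' @param te_meth_young,te_meth_old methylation of the youngest/oldest
#'   insertions; levels interpolate linearly in age.
#' @param viral_clusters,viral_cluster_genes,viral_cluster_methylated
#'   planted runs of consecutive virus-derived genes.
#' @param lambda_length,puc19_length spike-in contig lengths.
#' @param false_negative 1 - CpG methylation of the methylated control.
#' @param hit_noise fraction of host genes given a mixed
#'   eukaryote+prokaryote hit profile.
#' @param unassigned_fraction fraction of host genes whose only hits
#'   are within-genus (discarded on ingest, hence Unassigned).
#' @param self_genus genus of the simulated species.
#' @param n_hits hits per gene in the hit table.
#' @return validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L,
                            n_chroms = 8L, chrom_length = 600000L,
                            gc_content = 0.5,
                            n_genes = 5000L,
                            gene_length_meanlog = log(500),
                            gene_length_sdlog = 0.25,
                            gene_length_range = c(200L, 2000L),
                            intergenic_mean = 250,
                            methylated_gene_fraction = 0.02,
                            meth_beta = c(10, 2.5),
                            site_jitter = 0.05,
                            context_mode = "CG",
                            nonconversion = 0.003,
                            depth_mean = 30,
                            n_te_families = 3L,
                            te_insertions_per_family = 60L,
                            te_length_range = c(520L, 1500L),
                            te_age_range = c(0.02, 0.35),
                            te_ts_tv = 2,
                            te_meth_young = 0.8, te_meth_old = 0.1,
                            viral_clusters = 3L,
                            viral_cluster_genes = 8L,
                            viral_cluster_methylated = TRUE,
                            lambda_length = 48502L,
                            puc19_length = 2686L,
                            false_negative = 0.02,
                            hit_noise = 0.10,
                            unassigned_fraction = 0.02,
                            self_genus = "Simulatamoeba",
                            n_hits = 10L) {
  spec <- as.list(environment())
  fr <- c("gc_content", "methylated_gene_fraction", "site_jitter",
          "nonconversion", "false_negative", "hit_noise",
          "unassigned_fraction", "te_meth_young", "te_meth_old")
  for (f in fr)
    if (spec[[f]] < 0 || spec[[f]] > 1)
      stop(f, " must be a fraction in [0, 1]")
  if (spec$seed >= 2^31) stop("seed must be a 32-bit integer")
  structure(spec, class = "simulation_spec")
}

phase_seed <- function(seed, k)
  as.integer((abs(as.numeric(seed)) %% 100003) * 20011 + k * 104729) %%
    2147483647L

clip01 <- function(x) pmin(1, pmax(0, x))

#' Simulate a complete ground-truthed methylome bundle
#'
#' Generates genome, annotations, per-cytosine calls, hit table,
#' alignments and truth tables according to a [simulation_spec()].
#' With `dir` the bundle is also written to disk in the formats the
#' readers of this package consume (FASTA, GFF3, CGmap, TSV); the same
#' seed always produces a byte-identical bundle.
#'
#' @param spec a [simulation_spec()].
#' @param dir optional output directory (created if needed).
#' @return (invisibly when writing) list with elements `spec`,
#'   `genome` (DNAStringSet), `genes`, `tes` (feature tables),
#'   `sites` (site table), `hits_raw` (hit-table rows as on disk),
#'   `alignments`, `gene_truth`, `te_truth`, `genome_lengths`,
#'   and `paths` when `dir` was given.
#' @export
simulate_methylome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))

  ## ---- phase 1: feature placement --------------------------------
  set.seed(phase_seed(spec$seed, 1L))
  glen <- pmin(spec$gene_length_range[2],
               pmax(spec$gene_length_range[1],
                    round(rlnorm(spec$n_genes, spec$gene_length_meanlog,
                                 spec$gene_length_sdlog))))
  n_te <- spec$n_te_families * spec$te_insertions_per_family
  te_fams <- if (n_te > 0)
    rep(paste0(c("LINE", "LTR", "DNA", "Unknown"),
               "_sim")[seq_len(spec$n_te_families)],
        each = spec$te_insertions_per_family) else character()
  fam_age <- if (spec$n_te_families > 0)
    seq(spec$te_age_range[1], spec$te_age_range[2],
        length.out = spec$n_te_families) else numeric()
  te_age <- if (n_te > 0)
    pmax(0.005, rep(fam_age, each = spec$te_insertions_per_family) *
           runif(n_te, 0.7, 1.3)) else numeric()
  te_len <- if (n_te > 0)
    sample(spec$te_length_range[1]:spec$te_length_range[2], n_te,
           replace = TRUE) else integer()

  items <- data.table(
    id = c(sprintf("gene_%05d", seq_len(spec$n_genes)),
           if (n_te > 0) sprintf("te_%04d", seq_len(n_te))),
    kind = c(rep("gene", spec$n_genes), rep("TE", n_te)),
    len = c(glen, te_len),
    class_label = c(rep(NA_character_, spec$n_genes), te_fams),
    strand = sample(c("+", "-"), spec$n_genes + n_te, replace = TRUE)
  )
  items <- items[sample(.N)]
  gaps <- 20L + as.integer(round(rexp(nrow(items),
                                      1 / max(1, spec$intergenic_mean))))
  if (sum(as.numeric(items$len) + gaps) >
        spec$n_chroms * as.numeric(spec$chrom_length))
    stop("infeasible placement: features exceed genome capacity")
  chrom_id <- integer(nrow(items)); starts <- integer(nrow(items))
  ci <- 1L; cursor <- 0L
  for (i in seq_len(nrow(items))) {
    need <- gaps[i] + items$len[i]
    while (cursor + need > spec$chrom_length) {
      ci <- ci + 1L; cursor <- 0L
      if (ci > spec$n_chroms)
        stop("infeasible placement: features exceed genome capacity")
    }
    starts[i] <- cursor + gaps[i]
    chrom_id[i] <- ci
    cursor <- starts[i] + items$len[i]
  }
  items[, `:=`(chrom = paste0("chr", chrom_id), start = starts,
               end = starts + len)]
  setorderv(items, c("chrom", "start"))

  genes <- items[kind == "gene",
                 .(chrom, start, end, strand, id, kind, class_label)]
  tes <- items[kind == "TE",
               .(chrom, start, end, strand, id, kind, class_label)]
  te_meta <- items[kind == "TE", .(id)]
  if (n_te > 0) {
    ord <- match(te_meta$id, sprintf("te_%04d", seq_len(n_te)))
    te_meta[, `:=`(family = te_fams[ord], age = te_age[ord],
                   len = te_len[ord])]
  }

  ## viral clusters: runs of consecutive genes on one chromosome
  genes[, gidx := seq_len(.N), by = chrom]
  genes[, cluster := NA_character_]
  if (spec$viral_clusters > 0) {
    taxa <- rep(c("Mimivirus_sim", "Marseillevirus_sim",
                  "Chlorovirus_sim"),
                length.out = spec$viral_clusters)
    used <- list()
    for (cl in seq_len(spec$viral_clusters)) {
      placed <- FALSE
      for (try in 1:200) {
        ch <- sample(unique(genes$chrom), 1)
        ng <- genes[chrom == ch, .N]
        if (ng < spec$viral_cluster_genes) next
        i0 <- sample(ng - spec$viral_cluster_genes + 1L, 1)
        idx <- i0:(i0 + spec$viral_cluster_genes - 1L)
        key <- paste(ch, idx)
        if (any(key %in% unlist(used))) next
        used[[cl]] <- key
        genes[chrom == ch & gidx %in% idx,
              cluster := sprintf("cluster_%02d|%s", cl, taxa[cl])]
        placed <- TRUE
        break
      }
      if (!placed) stop("infeasible placement: cannot place viral cluster")
    }
  }
  genes[, viral := !is.na(cluster)]

  ## ---- phase 2: methylation truth --------------------------------
  set.seed(phase_seed(spec$seed, 2L))
  host_idx <- which(!genes$viral)
  n_meth_host <- round(spec$methylated_gene_fraction * length(host_idx))
  meth_host <- sample(host_idx, n_meth_host)
  genes[, methylated := FALSE]
  genes[meth_host, methylated := TRUE]
  if (spec$viral_cluster_methylated) genes[viral == TRUE, methylated := TRUE]
  genes[, true_level := spec$nonconversion]
  nm <- sum(genes$methylated)
  genes[methylated == TRUE,
        true_level := rbeta(nm, spec$meth_beta[1], spec$meth_beta[2])]
  if (n_te > 0) {
    aspan <- diff(spec$te_age_range)
    rel <- if (aspan > 0)
      clip01((te_meta$age - spec$te_age_range[1]) / aspan) else 0
    te_meta[, true_level := spec$te_meth_young +
              (spec$te_meth_old - spec$te_meth_young) * rel]
    te_meta[, methylated := true_level >=
              (spec$te_meth_young + spec$te_meth_old) / 2]
  }

  ## ---- phase 3: genome sequence ----------------------------------
  set.seed(phase_seed(spec$seed, 3L))
  pbase <- c((1 - spec$gc_content) / 2, spec$gc_content / 2,
             spec$gc_content / 2, (1 - spec$gc_content) / 2)
  rand_seq <- function(n) sample(c("A", "C", "G", "T"), n,
                                 replace = TRUE, prob = pbase)
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  seqs <- lapply(chroms, function(ch) rand_seq(spec$chrom_length))
  names(seqs) <- chroms

  ## TE consensus per family; insertions mutated under K2P-like rates
  alignments <- list()
  if (n_te > 0) {
    cons <- lapply(unique(te_fams), function(f)
      rand_seq(max(te_len)))
    names(cons) <- unique(te_fams)
    p_ts <- spec$te_ts_tv / (spec$te_ts_tv + 1)   # P/(P+Q) target
    TS <- c(A = "G", G = "A", C = "T", T = "C")
    TV <- list(A = c("C", "T"), G = c("C", "T"),
               C = c("A", "G"), T = c("A", "G"))
    for (i in seq_len(nrow(tes))) {
      te <- tes[i]; meta <- te_meta[id == te$id]
      src <- cons[[meta$family]][seq_len(meta$len)]
      mut <- runif(meta$len) < meta$age
      ins <- src
      if (any(mut)) {
        ts <- mut & runif(meta$len) < p_ts
        tv <- mut & !ts
        ins[ts] <- TS[src[ts]]
        ins[tv] <- vapply(src[tv], function(b) sample(TV[[b]], 1), "")
      }
      seqs[[te$chrom]][(te$start + 1L):te$end] <- ins
      alignments[[te$id]] <- insertion_alignment(
        te$id, meta$family, paste(src, collapse = ""),
        paste(ins, collapse = ""))
    }
  }
  seqs$lambda <- rand_seq(spec$lambda_length)
  seqs$pUC19 <- rand_seq(spec$puc19_length)

  ## ---- phase 4: per-cytosine truth and read counts ---------------
  set.seed(phase_seed(spec$seed, 4L))
  meth_feats <- rbind(
    genes[methylated == TRUE, .(chrom, start, end, true_level)],
    if (n_te > 0)
      merge(tes, te_meta[, .(id, true_level)],
            by = "id")[, .(chrom, start, end, true_level)]
    else NULL)
  meth_feats <- meth_feats[true_level > 0]   # level-0 features are background
  site_list <- vector("list", length(seqs))
  names(site_list) <- names(seqs)
  for (ch in names(seqs)) {
    s <- seqs[[ch]]
    wpos <- which(s == "C") - 1L          # 0-based
    cpos <- which(s == "G") - 1L
    pos <- c(wpos, cpos)
    strand <- c(rep("+", length(wpos)), rep("-", length(cpos)))
    o <- order(pos)
    pos <- pos[o]; strand <- strand[o]
    ctx <- context_from_chars(s, pos, strand, ch)
    p <- rep(spec$nonconversion, length(pos))
    if (ch == "pUC19") {
      cg <- !is.na(ctx$trinuc) & ctx$trinuc == "CG"
      p[cg] <- 1 - spec$false_negative
    } else if (ch != "lambda" && nrow(meth_feats) > 0) {
      mf <- meth_feats[chrom == ch]
      if (nrow(mf)) {
        sel <- context_filter(
          data.table(dinuc = ctx$dinuc, trinuc = ctx$trinuc),
          spec$context_mode)
        for (j in seq_len(nrow(mf))) {
          lo <- findInterval(mf$start[j] - 0.5, pos) + 1L
          hi <- findInterval(mf$end[j] - 0.5, pos)
          if (hi < lo) next
          idx <- lo:hi
          idx <- idx[sel[idx]]
          if (!length(idx)) next
          p[idx] <- clip01(mf$true_level[j] +
                             runif(length(idx), -spec$site_jitter,
                                   spec$site_jitter))
        }
      }
    }
    depth <- rpois(length(pos), spec$depth_mean)
    keep <- depth > 0L
    site_list[[ch]] <- data.table(
      chrom = ch, pos = pos[keep], strand = strand[keep],
      dinuc = ctx$dinuc[keep], trinuc = ctx$trinuc[keep],
      n_meth = rbinom(sum(keep), depth[keep], p[keep]),
      n_total = depth[keep])
  }
  sites <- rbindlist(site_list)
  validate_sites(sites)

  ## ---- phase 5: hit table ----------------------------------------
  set.seed(phase_seed(spec$seed, 5L))
  euk_pool <- paste0("Eukgenus", sprintf("%02d", 1:20))
  prok_pool <- paste0("Bacgenus", sprintf("%02d", 1:10))
  n_host <- sum(!genes$viral)
  host_cat <- sample(c("Unassigned", "Eukaryote+Prokaryote", "Eukaryote"),
                     n_host, replace = TRUE,
                     prob = c(spec$unassigned_fraction, spec$hit_noise,
                              1 - spec$unassigned_fraction -
                                spec$hit_noise))
  genes[, category := "Virus"]
  genes[viral == FALSE, category := host_cat]
  hit_rows <- genes[, {
    nh <- spec$n_hits
    lin <- switch(category,
      Virus = paste0("Viruses;Nucleocytoviricota;Megaviricetes;",
                     sub(".*\\|", "", cluster)),
      Unassigned = paste0("Eukaryota;Amoebozoa;Discosea;",
                          spec$self_genus),
      `Eukaryote+Prokaryote` = c(
        paste0("Eukaryota;Amoebozoa;Tubulinea;",
               sample(euk_pool, 6, replace = TRUE)),
        paste0("Bacteria;Pseudomonadota;Gammaproteobacteria;",
               sample(prok_pool, 4, replace = TRUE))),
      paste0("Eukaryota;Amoebozoa;Tubulinea;",
             sample(euk_pool, nh, replace = TRUE)))
    .(taxonomy = rep_len(lin, nh),
      bitscore = round(sort(runif(nh, 80, 500), decreasing = TRUE), 1),
      evalue = signif(10^runif(nh, -40, -4), 3))
  }, by = .(gene_id = id)]

  ## ---- truth tables ----------------------------------------------
  gene_truth <- genes[, .(gene_id = id, chrom, start, end, strand,
                          methylated, true_level, category,
                          cluster = sub("\\|.*", "", cluster))]
  te_truth <- if (n_te > 0)
    merge(tes[, .(te_id = id, chrom, start, end, strand)],
          te_meta[, .(te_id = id, family, length = len, age,
                      true_level, methylated)],
          by = "te_id")
  else data.table()

  genome <- Biostrings::DNAStringSet(
    vapply(seqs, paste, "", collapse = ""))
  genome_lengths <- setNames(lengths(seqs), names(seqs))
  genes_out <- genes[, .(chrom, start, end, strand, id, kind,
                         class_label)]
  bundle <- list(spec = spec, genome = genome,
                 genome_lengths = genome_lengths,
                 genes = genes_out, tes = tes, sites = sites,
                 hits_raw = hit_rows, alignments = alignments,
                 gene_truth = gene_truth, te_truth = te_truth)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      genome = file.path(dir, "genome.fa"),
      genes = file.path(dir, "genes.gff3"),
      tes = file.path(dir, "tes.gff3"),
      cgmap = file.path(dir, "calls.cgmap"),
      hits = file.path(dir, "hits.tsv"),
      alignments = file.path(dir, "tes.aln"),
      gene_truth = file.path(dir, "gene_truth.tsv"),
      te_truth = file.path(dir, "te_truth.tsv"),
      spec = file.path(dir, "spec.json"))
    Biostrings::writeXStringSet(genome, paths$genome)
    write_gff3(genes_out, paths$genes, type = "gene")
    if (n_te > 0) write_gff3(tes, paths$tes, type = "dispersed_repeat")
    write_cgmap(sites, paths$cgmap)
    fwrite(hit_rows, paths$hits, sep = "\t", quote = FALSE)
    writeLines(as.character(unlist(lapply(alignments, function(a)
      c(paste0(">", a$te_id, "\t", a$family), a$consensus,
        a$insertion)))), paths$alignments)
    fwrite(gene_truth, paths$gene_truth, sep = "\t", quote = FALSE)
    fwrite(te_truth, paths$te_truth, sep = "\t", quote = FALSE)
    jsonlite::write_json(unclass(spec), paths$spec, auto_unbox = TRUE,
                         digits = NA)
    bundle$paths <- paths
    return(invisible(bundle))
  }
  bundle
}
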