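#' Read-count-weighted methylation level
#'
#' The level of a set of sites is the pooled fraction
#' \eqn{\sum m_i / \sum t_i} over sites passing the context filter with
#' coverage at least `min_cov` — weighting by reads, not averaging
#' per-site fractions, so the estimate is robust to uneven coverage.
#' Zero qualifying reads yields an explicitly undefined level, never a
#' silent 0.
#'
#' @param sites site table, already restricted to the region of
#'   interest.
#' @param context_mode see [context_filter()]. Default "CX" (all
#'   cytosines).
#' @param min_cov minimum per-site total coverage (default 1).
#' @return a [new_weighted_level()] object.
#' @export
weighted_level <- function(sites, context_mode = "CX", min_cov = 1L) {
  keep <- context_filter(sites, context_mode) &
    sites$n_total >= max(1L, min_cov)
  new_weighted_level(sum(as.numeric(sites$n_meth[keep])),
                     sum(as.numeric(sites$n_total[keep])),
                     sum(keep))
}

#' Global methylation levels per sequence context
#'
#' One weighted level per dinucleotide context (CA, CC, CG, CT), per
#' trinucleotide context (CG, CHG, CHH) and for all cytosines (CX),
#' after excluding spike-in contigs.
#'
#' @param sites genome-wide site table.
#' @param exclude_contigs contig names to drop (spike-in controls).
#' @param min_cov minimum per-site coverage.
#' @return `data.table` with columns context, level, n_sites,
#'   n_meth_reads, n_total_reads, defined.
#' @export
global_context_levels <- function(sites, exclude_contigs = character(),
                                  min_cov = 1L) {
  x <- sites[!chrom %in% exclude_contigs]
  one <- function(ctx, filt) {
    wl <- weighted_level(x[filt], "CX", min_cov)
    data.table(context = ctx, level = wl$level, n_sites = wl$n_sites,
               n_meth_reads = wl$n_meth_reads,
               n_total_reads = wl$n_total_reads, defined = wl$defined)
  }
  rbindlist(c(
    lapply(c("CA", "CC", "CG", "CT"), function(d)
      one(paste0("dinuc_", d), !is.na(x$dinuc) & x$dinuc == d)),
    lapply(c("CG", "CHG", "CHH"), function(tr)
      one(tr, !is.na(x$trinuc) & x$trinuc == tr)),
    list(one("CX", rep(TRUE, nrow(x))))
  ))
}

#' Spike-in conversion quality control
#'
#' The non-conversion (false positive) rate is the all-cytosine
#' weighted level on a fully unmethylated control (lambda phage); the
#' false-negative rate is 1 minus the CpG-context level on a fully
#' CpG-methylated control (pUC19).
#'
#' @param sites site table containing the control contigs.
#' @param unmethylated_contig,methylated_contig contig names.
#' @param min_cov minimum per-site coverage.
#' @return object of class `spike_in_qc`.
#' @export
spike_in_qc <- function(sites, unmethylated_contig = "lambda",
                        methylated_contig = "pUC19", min_cov = 1L) {
  for (ctg in c(unmethylated_contig, methylated_contig))
    if (!any(sites$chrom == ctg))
      stop("spike-in contig not found in site stream: ", ctg)
  un <- weighted_level(sites[chrom == unmethylated_contig], "CX", min_cov)
  me <- weighted_level(sites[chrom == methylated_contig], "CG", min_cov)
  structure(list(
    nonconversion_rate = un$level,
    false_negative_rate = if (me$defined) 1 - me$level else NA_real_,
    n_sites_unmethylated = un$n_sites,
    n_sites_methylated = me$n_sites,
    unmethylated_level = un, methylated_level = me
  ), class = "spike_in_qc")
}

#' @export
print.spike_in_qc <- function(x, ...) {
  cat(sprintf(
    "spike-in QC\n  non-conversion: %.4f%% (%d sites)\n  false negative: %.4f%% (%d CpG sites)\n",
    100 * x$nonconversion_rate, x$n_sites_unmethylated,
    100 * x$false_negative_rate, x$n_sites_methylated))
  invisible(x)
}

#' CpG dyad methylation symmetry
#'
#' A dyad pairs the Watson-strand cytosine of a CpG at position i with
#' the Crick-strand cytosine at i+1. High correlation of the two
#' per-site levels indicates maintenance-type (symmetric) methylation.
#'
#' @param sites site table; only CG-trinucleotide sites are used.
#' @param min_cov minimum coverage per strand member (default 5; the
#'   estimate is noise-dominated at low coverage).
#' @return object of class `dyad_symmetry` with Pearson `r` and
#'   `n_dyads`.
#' @export
dyad_symmetry <- function(sites, min_cov = 5L) {
  cg <- sites[!is.na(trinuc) & trinuc == "CG" & n_total >= min_cov]
  plus <- cg[strand == "+", .(chrom, pos, lp = n_meth / n_total)]
  minus <- cg[strand == "-", .(chrom, pos = pos - 1L,
                               lm = n_meth / n_total)]
  dy <- merge(plus, minus, by = c("chrom", "pos"))
  if (nrow(dy) < 2L)
    stop("fewer than 2 CpG dyads pass the coverage filter")
  structure(list(r = cor(dy$lp, dy$lm), n_dyads = nrow(dy)),
            class = "dyad_symmetry")
}

#' @export
print.dyad_symmetry <- function(x, ...) {
  cat(sprintf("CpG dyad symmetry: r = %.3f over %d dyads\n",
              x$r, x$n_dyads))
  invisible(x)
}
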