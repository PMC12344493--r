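#' Construct a table of strand-resolved cytosine sites
#'
#' The atom of every methylation computation: one row per cytosine per
#' strand, with methylated/total read counts and sequence context.
#' A CpG dyad therefore yields two rows (one per strand).
#'
#' @param chrom character chromosome/contig names.
#' @param pos integer 0-based genomic coordinate of the cytosine.
#' @param strand "+" (Watson C) or "-" (Crick C, i.e. Watson G).
#' @param dinuc dinucleotide context, one of "CA","CC","CG","CT" or NA.
#' @param trinuc trinucleotide context, one of "CG","CHG","CHH" or NA.
#'   H stands for A, C or T.
#' @param n_meth,n_total non-negative integer read counts with
#'   `n_meth <= n_total`.
#' @return a `data.table` with columns chrom, pos, strand, dinuc,
#'   trinuc, n_meth, n_total.
#' @export
methyl_sites <- function(chrom, pos, strand,
                         dinuc = NA_character_, trinuc = NA_character_,
                         n_meth, n_total) {
  dt <- data.table(
    chrom = as.character(chrom), pos = as.integer(pos),
    strand = as.character(strand),
    dinuc = as.character(dinuc), trinuc = as.character(trinuc),
    n_meth = as.integer(n_meth), n_total = as.integer(n_total)
  )
  validate_sites(dt)
  dt[]
}

SITE_COLS <- c("chrom", "pos", "strand", "dinuc", "trinuc",
               "n_meth", "n_total")

validate_sites <- function(sites) {
  if (!is.data.frame(sites) || !all(SITE_COLS %in% names(sites)))
    stop("sites must be a data.frame with columns: ",
         paste(SITE_COLS, collapse = ", "))
  if (any(!sites$strand %in% c("+", "-")))
    stop("site strand must be '+' or '-'")
  if (any(sites$pos < 0L)) stop("site pos must be >= 0 (0-based)")
  if (any(sites$n_meth < 0L) || any(sites$n_total < 0L))
    stop("read counts must be non-negative")
  bad <- which(sites$n_meth > sites$n_total)
  if (length(bad))
    stop("n_meth > n_total at row(s) ", paste(head(bad, 5), collapse = ", "))
  ok_di <- is.na(sites$dinuc) | sites$dinuc %in% c("CA", "CC", "CG", "CT")
  if (!all(ok_di)) stop("dinuc context must be CA/CC/CG/CT or NA")
  ok_tri <- is.na(sites$trinuc) | sites$trinuc %in% c("CG", "CHG", "CHH")
  if (!all(ok_tri)) stop("trinuc context must be CG/CHG/CHH or NA")
  invisible(sites)
}

#' Construct a table of genomic features
#'
#' Intervals are 0-based half-open `[start, end)`, the internal
#' convention throughout the package.
#'
#' @param chrom character contig names.
#' @param start,end integer interval bounds, `0 <= start < end`.
#' @param strand "+", "-" or "." (unstranded).
#' @param id unique feature identifiers.
#' @param kind one of "gene", "TE", "window", "region", "spike_in".
#' @param class_label free-text class (e.g. a TE family such as
#'   LINE/LTR/DNA/Unknown); NA where not applicable.
#' @return a `data.table` with one row per feature.
#' @export
features <- function(chrom, start, end, strand = ".", id,
                     kind = "gene", class_label = NA_character_) {
  dt <- data.table(
    chrom = as.character(chrom), start = as.integer(start),
    end = as.integer(end), strand = as.character(strand),
    id = as.character(id), kind = as.character(kind),
    class_label = as.character(class_label)
  )
  validate_features(dt)
  dt[]
}

FEATURE_COLS <- c("chrom", "start", "end", "strand", "id", "kind",
                  "class_label")

validate_features <- function(feats) {
  if (!is.data.frame(feats) || !all(FEATURE_COLS %in% names(feats)))
    stop("features must have columns: ",
         paste(FEATURE_COLS, collapse = ", "))
  if (any(feats$start < 0L)) stop("feature start must be >= 0")
  if (any(feats$start >= feats$end))
    stop("feature start must be < end (0-based half-open)")
  if (any(!feats$strand %in% c("+", "-", ".")))
    stop("feature strand must be '+', '-' or '.'")
  dup <- unique(feats$id[duplicated(feats$id)])
  if (length(dup))
    stop("duplicate feature ids: ", paste(head(dup, 10), collapse = ", "))
  invisible(feats)
}

#' Weighted methylation level of a set of sites
#'
#' @param n_meth_reads,n_total_reads pooled read counts.
#' @param n_sites number of covered cytosines pooled.
#' @return an object of class `weighted_level` with fields `level`
#'   (= n_meth_reads / n_total_reads), `n_sites`, `n_meth_reads`,
#'   `n_total_reads` and `defined` (FALSE when no reads: the level is
#'   then NA, never silently 0).
#' @export
new_weighted_level <- function(n_meth_reads, n_total_reads, n_sites) {
  defined <- n_total_reads > 0
  structure(list(
    level = if (defined) n_meth_reads / n_total_reads else NA_real_,
    n_sites = as.integer(n_sites),
    n_meth_reads = as.numeric(n_meth_reads),
    n_total_reads = as.numeric(n_total_reads),
    defined = defined
  ), class = "weighted_level")
}

#' @export
print.weighted_level <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("weighted 5mC level: %.4f (%d sites, %g/%g reads)\n",
                x$level, x$n_sites, x$n_meth_reads, x$n_total_reads))
  } else {
    cat(sprintf("weighted 5mC level: undefined (%d sites, 0 reads)\n",
                x$n_sites))
  }
  invisible(x)
}

#' Select sites matching a context mode
#'
#' Context modes: `"CG"`, `"CHG"`, `"CHH"` match the trinucleotide
#' context; `"CX"` matches every cytosine regardless of context;
#' `"nonCG"` matches CHG and CHH; a character vector of dinucleotides
#' (any subset of CA/CC/CG/CT) matches on the dinucleotide context.
#'
#' @param sites a site table (see [methyl_sites()]).
#' @param context_mode mode string or dinucleotide set.
#' @return logical vector along rows of `sites`.
#' @export
context_filter <- function(sites, context_mode) {
  if (length(context_mode) == 1L &&
      context_mode %in% c("CG", "CHG", "CHH", "CX", "nonCG")) {
    switch(context_mode,
      CX    = rep(TRUE, nrow(sites)),
      nonCG = !is.na(sites$trinuc) & sites$trinuc != "CG",
      !is.na(sites$trinuc) & sites$trinuc == context_mode
    )
  } else {
    bad <- setdiff(context_mode, c("CA", "CC", "CG", "CT"))
    if (length(bad))
      stop("unknown context mode: ", paste(bad, collapse = ", "))
    !is.na(sites$dinuc) & sites$dinuc %in% context_mode
  }
}
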