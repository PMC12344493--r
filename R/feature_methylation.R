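#' Per-feature weighted methylation levels
#'
#' One weighted level per feature over the sites intersecting its span
#' `[start, end)` in the requested context. The gene body is the full
#' annotated span, introns included; promoters are not masked (in the
#' silencing-type methylomes this package targets, methylation extends
#' across body and promoter alike). Features with no qualifying site
#' get an undefined level and status "undetermined"; they are excluded
#' from threshold fitting and from enrichment denominators downstream.
#'
#' @param sites site table.
#' @param feats feature table.
#' @param context_mode context used for the level, chosen per species
#'   to match the silencing-associated context ("CG" for
#'   CpG-dominated methylomes, "CX" when all contexts carry signal,
#'   "CHG"/"nonCG" where those mark silencing).
#' @param min_cov minimum per-site coverage.
#' @return `data.table`: feature_id, chrom, start, end, strand, kind,
#'   class_label, context_mode, level, n_sites, n_meth_reads,
#'   n_total_reads, status ("undetermined" or NA, to be set by
#'   [classify_features()]).
#' @export
summarize_features <- function(sites, feats, context_mode = "CG",
                               min_cov = 1L) {
  validate_features(feats)
  if (nrow(feats) == 0L) stop("no features supplied")
  x <- sites[context_filter(sites, context_mode) &
               sites$n_total >= max(1L, min_cov),
             .(chrom, pos, n_meth, n_total)]
  f <- as.data.table(feats)[, .(chrom, start, end, strand, id, kind,
                                class_label)]
  x[, `:=`(s = pos, e = pos)]        # point query, closed-interval join
  f2 <- f[, .(chrom, start, end2 = end - 1L, id)]
  setkey(f2, chrom, start, end2)
  ov <- foverlaps(x, f2, by.x = c("chrom", "s", "e"),
                  by.y = c("chrom", "start", "end2"),
                  type = "within", nomatch = NULL)
  agg <- ov[, .(n_sites = .N, m = sum(as.numeric(n_meth)),
                t = sum(as.numeric(n_total))), by = id]
  out <- merge(f, agg, by = "id", all.x = TRUE)
  out[is.na(n_sites), `:=`(n_sites = 0L, m = 0, t = 0)]
  out[, `:=`(
    level = ifelse(t > 0, m / t, NA_real_),
    context_mode = paste(context_mode, collapse = ","),
    status = ifelse(t > 0, NA_character_, "undetermined")
  )]
  setnames(out, c("id", "m", "t"),
           c("feature_id", "n_meth_reads", "n_total_reads"))
  setcolorder(out, c("feature_id", "chrom", "start", "end", "strand",
                     "kind", "class_label", "context_mode", "level",
                     "n_sites", "n_meth_reads", "n_total_reads",
                     "status"))
  setorderv(out, c("chrom", "start"))
  out[]
}

#' Data-driven methylated/unmethylated threshold selection
#'
#' Two routes, mirroring how such thresholds are chosen and validated
#' in practice:
#'
#' 1. *Valley*: a fixed-width histogram of levels is scanned for its
#'    two highest-density modes; the threshold is the midpoint of the
#'    lowest-density bin strictly between them. Among tied lowest bins
#'    the one whose midpoint is closest to the midpoint of the mean
#'    levels on either side is taken (then the lower) — the cut that
#'    best separates the two populations.
#'    The distribution is called bimodal when that valley bin's count
#'    is below half the smaller mode's count and the modes are not
#'    adjacent.
#' 2. *k-means (k = 2)* on the 1-D levels, deterministically
#'    initialised at the data min and max, Lloyd iterations to
#'    convergence, ties assigned to the lower centre; the boundary is
#'    the midpoint of the final centres.
#'
#' The chosen threshold is the valley when the distribution is
#' bimodal, otherwise the k-means boundary.
#'
#' @param levels numeric vector of per-feature levels in \[0, 1\]
#'   (undefined levels removed); at least 20 required.
#' @param bin_width histogram bin width (default 0.05).
#' @return object of class `threshold_report`: valley_threshold,
#'   kmeans_boundary, kmeans_centers (ascending), chosen_threshold,
#'   bimodality_flag.
#' @export
select_threshold <- function(levels, bin_width = 0.05) {
  levels <- levels[!is.na(levels)]
  if (length(levels) < 20L)
    stop("need at least 20 defined levels to select a threshold")
  if (any(levels < 0 | levels > 1)) stop("levels must lie in [0, 1]")
  if (diff(range(levels)) < 1e-12)
    stop("all levels identical: no threshold can be selected")

  breaks <- seq(0, 1, by = bin_width)
  if (tail(breaks, 1) < 1) breaks <- c(breaks, 1)
  cnt <- tabulate(pmin(findInterval(levels, breaks, left.open = FALSE,
                                    rightmost.closed = TRUE),
                       length(breaks) - 1L),
                  nbins = length(breaks) - 1L)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  padded <- c(-Inf, cnt, -Inf)
  locmax <- which(cnt > 0 &
                    cnt >= padded[seq_along(cnt)] &
                    cnt >= padded[seq_along(cnt) + 2L])
  ## collapse plateau runs of equal-count adjacent maxima to one bin
  if (length(locmax) > 1L) {
    runs <- cumsum(c(TRUE, diff(locmax) > 1L |
                       cnt[locmax[-1]] != cnt[locmax[-length(locmax)]]))
    locmax <- vapply(split(locmax, runs), function(ix)
      ix[ceiling(length(ix) / 2)], integer(1))
  }
  valley <- NA_real_; bimodal <- FALSE
  if (length(locmax) >= 2L) {
    top2 <- locmax[order(-cnt[locmax], locmax)][1:2]
    m1 <- min(top2); m2 <- max(top2)
    if (m2 > m1 + 1L) {
      between <- (m1 + 1L):(m2 - 1L)
      vmin <- min(cnt[between])
      tied <- between[cnt[between] == vmin]
      ## tie-break: the cut that best separates the two populations —
      ## the tied bin whose midpoint is closest to the midpoint of the
      ## mean levels on either side of it
      score <- vapply(tied, function(tb) {
        lo <- levels[levels < breaks[tb]]
        hi <- levels[levels >= breaks[tb + 1L]]
        abs(mids[tb] - (mean(lo) + mean(hi)) / 2)
      }, numeric(1))
      vb <- tied[order(score, tied)][1]
      valley <- mids[vb]
      bimodal <- vmin < 0.5 * min(cnt[m1], cnt[m2])
    }
  }

  km <- kmeans2_1d(levels)
  chosen <- if (bimodal && !is.na(valley)) valley else km$boundary
  structure(list(valley_threshold = valley,
                 kmeans_boundary = km$boundary,
                 kmeans_centers = km$centers,
                 chosen_threshold = chosen,
                 bimodality_flag = bimodal,
                 bin_width = bin_width,
                 n_levels = length(levels)),
            class = "threshold_report")
}

## deterministic 1-D Lloyd k-means, k = 2, centres init at min/max,
## ties toward the lower centre
kmeans2_1d <- function(x, max_iter = 100L) {
  c1 <- min(x); c2 <- max(x)
  for (i in seq_len(max_iter)) {
    low <- abs(x - c1) <= abs(x - c2)
    n1 <- mean(x[low]); n2 <- mean(x[!low])
    if (!any(!low)) n2 <- c2
    if (isTRUE(all.equal(c(n1, n2), c(c1, c2), tolerance = 1e-12))) break
    c1 <- n1; c2 <- n2
  }
  list(centers = sort(c(c1, c2)), boundary = (c1 + c2) / 2)
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf(
    paste0("threshold report (n = %d)\n  valley: %s  (bimodal: %s)\n",
           "  k-means centres: %.3f / %.3f, boundary %.3f\n",
           "  chosen threshold: %.3f\n"),
    x$n_levels,
    if (is.na(x$valley_threshold)) "NA"
    else sprintf("%.3f", x$valley_threshold),
    x$bimodality_flag, x$kmeans_centers[1], x$kmeans_centers[2],
    x$kmeans_boundary, x$chosen_threshold))
  invisible(x)
}

#' Assign methylated/unmethylated status at a threshold
#'
#' Status is "methylated" iff the level is defined and `>= threshold`
#' (inclusive, matching the ">= x%" convention of published
#' per-species cut-offs); undefined levels stay "undetermined".
#'
#' @param summaries output of [summarize_features()].
#' @param threshold fraction in (0, 1).
#' @return the summaries with `status` set; attributes `n_methylated`,
#'   `n_unmethylated`, `n_undetermined` and `fraction_methylated`
#'   (methylated / determined).
#' @export
classify_features <- function(summaries, threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  out <- copy(as.data.table(summaries))
  out[, status := ifelse(is.na(level), "undetermined",
                         ifelse(level >= threshold, "methylated",
                                "unmethylated"))]
  nm <- sum(out$status == "methylated")
  nu <- sum(out$status == "unmethylated")
  setattr(out, "n_methylated", nm)
  setattr(out, "n_unmethylated", nu)
  setattr(out, "n_undetermined", sum(out$status == "undetermined"))
  setattr(out, "fraction_methylated",
          if (nm + nu > 0) nm / (nm + nu) else NA_real_)
  out[]
}

#' Filter transposable-element insertions and families for reporting
#'
#' Insertions shorter than `min_len` are discarded before any counting
#' (to avoid spurious small annotations); a family (by `class_label`)
#' is retained only when at least `min_meth_insertions` of its
#' remaining insertions are methylated at `threshold`.
#'
#' @param te_summaries [summarize_features()] output for TE insertions
#'   (class_label = family).
#' @param threshold methylated/unmethylated cut-off.
#' @param min_len minimum insertion length in bp (default 500).
#' @param min_meth_insertions minimum methylated insertions per family
#'   (default 20).
#' @return list: `families` (retained family labels), `insertions`
#'   (classified table restricted to retained families), `counts`
#'   (per-family methylated/total insertion counts after the length
#'   filter).
#' @export
filter_te_set <- function(te_summaries, threshold, min_len = 500L,
                          min_meth_insertions = 20L) {
  x <- as.data.table(te_summaries)[end - start >= min_len]
  x <- classify_features(x, threshold)
  counts <- x[, .(n_insertions = .N,
                  n_methylated = sum(status == "methylated")),
              by = class_label]
  keep <- counts[n_methylated >= min_meth_insertions, class_label]
  list(families = keep,
       insertions = x[class_label %in% keep],
       counts = counts[])
}
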