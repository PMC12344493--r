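#' Average methylation metaprofile over features
#'
#' Each feature body is scaled to `body_bins` bins; upstream and
#' downstream flanks are fixed `flank_bp` windows split into
#' `flank_bins` bins each. Sites are assigned to bins by position
#' (features shorter than `body_bins` simply map their sites through
#' the fractional position, they are not dropped), minus-strand
#' features are reversed so bin 1 is always the 5' end, and read
#' counts are pooled across features within a bin — the same weighted
#' averaging used everywhere else (a mean-of-feature-means variant, as
#' computed by coverage-track tools, would weight features equally
#' instead; see the methods vignette).
#'
#' @param sites site table.
#' @param feats feature table (strand-resolved; "." is treated as "+").
#' @param body_bins number of bins over the scaled body.
#' @param flank_bp flank size in bp on each side.
#' @param flank_bins bins per flank (0 disables flanks).
#' @param context_mode see [context_filter()].
#' @param min_cov minimum per-site coverage.
#' @return object of class `metaprofile`: list with `level` (numeric
#'   vector of length `2*flank_bins + body_bins`), `zone` labels,
#'   pooled `n_meth_reads`, `n_total_reads`, `n_sites` per bin.
#' @export
metaprofile <- function(sites, feats, body_bins = 20L, flank_bp = 2000L,
                        flank_bins = 10L, context_mode = "CG",
                        min_cov = 1L) {
  validate_features(feats)
  if (flank_bins > 0L && flank_bp <= 0L)
    stop("flank_bp must be positive when flank_bins > 0")
  x <- sites[context_filter(sites, context_mode) &
               sites$n_total >= max(1L, min_cov),
             .(chrom, pos, n_meth, n_total)]
  f <- as.data.table(feats)[, .(chrom, start, end, strand, id)]
  f[, `:=`(span_start = start - ifelse(flank_bins > 0L, flank_bp, 0L),
           span_end = end + ifelse(flank_bins > 0L, flank_bp, 0L))]
  x[, `:=`(s = pos, e = pos + 1L)]
  setkey(f, chrom, span_start, span_end)
  ov <- foverlaps(x, f, by.x = c("chrom", "s", "e"),
                  by.y = c("chrom", "span_start", "span_end"),
                  type = "within", nomatch = NULL)
  nb <- 2L * flank_bins + body_bins
  if (nrow(ov) == 0L) {
    lev <- rep(NA_real_, nb)
  } else {
    ov[, bin := {
      b <- integer(.N)
      up <- pos < start
      dn <- pos >= end
      body <- !up & !dn
      b[up] <- pmin(flank_bins - 1L,
                    as.integer(floor((pos[up] - span_start[up]) /
                                       flank_bp * flank_bins)))
      b[body] <- flank_bins +
        pmin(body_bins - 1L,
             as.integer(floor((pos[body] - start[body]) /
                                (end[body] - start[body]) * body_bins)))
      b[dn] <- flank_bins + body_bins +
        pmin(flank_bins - 1L,
             as.integer(floor((pos[dn] - end[dn]) /
                                flank_bp * flank_bins)))
      ifelse(strand == "-", nb - 1L - b, b)
    }]
    agg <- ov[, .(m = sum(as.numeric(n_meth)),
                  t = sum(as.numeric(n_total)), ns = .N), keyby = bin]
    lev <- rep(NA_real_, nb); mm <- tt <- ss <- numeric(nb)
    mm[agg$bin + 1L] <- agg$m; tt[agg$bin + 1L] <- agg$t
    ss[agg$bin + 1L] <- agg$ns
    lev[tt > 0] <- mm[tt > 0] / tt[tt > 0]
  }
  if (nrow(ov) == 0L) mm <- tt <- ss <- numeric(nb)
  zone <- c(rep("upstream", flank_bins), rep("body", body_bins),
            rep("downstream", flank_bins))
  structure(list(level = lev, zone = zone, n_meth_reads = mm,
                 n_total_reads = tt, n_sites = as.integer(ss),
                 body_bins = body_bins, flank_bins = flank_bins,
                 flank_bp = flank_bp, context_mode = context_mode),
            class = "metaprofile")
}

#' @export
print.metaprofile <- function(x, ...) {
  cat(sprintf("metaprofile (%s): %d flank + %d body + %d flank bins\n",
              paste(x$context_mode, collapse = ","),
              x$flank_bins, x$body_bins, x$flank_bins))
  print(round(x$level, 4))
  invisible(x)
}
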