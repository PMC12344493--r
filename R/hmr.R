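#' Call hypermethylated regions by sliding windows
#'
#' Each chromosome is tiled with windows `[k*step, k*step + window)`
#' (clipped at the chromosome end). A window is retained when its
#' weighted methylation level in `context_mode` is strictly greater
#' than `min_level` and it contains at least `min_sites` covered
#' cytosines (windows with no covered cytosine cannot pass and are
#' dropped). Retained windows that overlap or abut are merged into
#' maximal regions; with `step < window` adjacent passing windows
#' always overlap, the book-ended case only arises at clipped
#' chromosome ends. Each region's mean level is recomputed from the
#' pooled counts over its full merged span.
#'
#' @param sites site table.
#' @param genome_lengths named integer vector of chromosome lengths;
#'   every chromosome present in `sites` must be named here.
#' @param window window size in bp (default 500).
#' @param step window step in bp (default 250, i.e. 250 bp overlap);
#'   must be `<= window`.
#' @param min_level strict lower bound on the window level
#'   (default 0.10, i.e. ">10% mC").
#' @param context_mode see [context_filter()].
#' @param min_cov minimum per-site coverage for a site to count.
#' @param min_sites minimum covered cytosines per window (default 5,
#'   suppressing single-site windows).
#' @return `data.table` of regions: id, chrom, start, end, mean_level,
#'   n_windows, n_sites — per chromosome pairwise disjoint and sorted.
#' @export
call_hypermethylated_regions <- function(sites, genome_lengths,
                                         window = 500L, step = 250L,
                                         min_level = 0.10,
                                         context_mode = "CG",
                                         min_cov = 1L, min_sites = 5L) {
  if (step > window) stop("step must be <= window")
  if (min_level <= 0 || min_level >= 1) stop("min_level must be in (0,1)")
  empty <- data.table(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      mean_level = numeric(), n_windows = integer(),
                      n_sites = integer())
  if (nrow(sites) == 0L) return(empty)
  missing_chr <- setdiff(unique(sites$chrom), names(genome_lengths))
  if (length(missing_chr))
    stop("chromosome(s) in sites absent from genome_lengths: ",
         paste(missing_chr, collapse = ", "))
  x <- sites[context_filter(sites, context_mode) &
               sites$n_total >= max(1L, min_cov),
             .(chrom, pos, n_meth, n_total)]
  if (nrow(x) == 0L) return(empty)

  ## window indices covering each site: k*step <= pos < k*step+window
  x[, `:=`(kmin = pmax(0L, as.integer(ceiling((pos - window + 1L) / step))),
           kmax = as.integer(floor(pos / step)))]
  x[, kmax := pmin(kmax,
                   as.integer(floor((genome_lengths[chrom] - 1L) / step)))]
  x <- x[kmax >= kmin]
  nrep <- x$kmax - x$kmin + 1L
  wins <- x[rep(seq_len(.N), nrep)]
  wins[, k := unlist(mapply(seq.int, x$kmin, x$kmax, SIMPLIFY = FALSE))]
  agg <- wins[, .(m = sum(as.numeric(n_meth)),
                  t = sum(as.numeric(n_total)), ns = .N),
              by = .(chrom, k)]
  agg <- agg[t > 0 & m / t > min_level & ns >= min_sites]
  if (nrow(agg) == 0L) return(empty)
  agg[, `:=`(win_start = k * step,
             win_end = pmin(k * step + window,
                            as.integer(genome_lengths[chrom])))]
  setorderv(agg, c("chrom", "win_start"))

  ## merge overlapping or book-ended windows
  agg[, region := cumsum(c(1L, ifelse(
    chrom[-1] == chrom[-.N] & win_start[-1] <= win_end[-.N], 0L, 1L))),
    by = NULL]
  reg <- agg[, .(chrom = chrom[1], start = min(win_start),
                 end = max(win_end), n_windows = .N), by = region]

  ## recompute pooled level over each merged span
  setkey(reg, chrom, start, end)
  x[, `:=`(s = pos, e = pos)]
  reg2 <- copy(reg)[, end2 := end - 1L]
  setkey(reg2, chrom, start, end2)
  ov <- foverlaps(x, reg2, by.x = c("chrom", "s", "e"),
                  by.y = c("chrom", "start", "end2"),
                  type = "within", nomatch = NULL)
  lv <- ov[, .(mean_level = sum(as.numeric(n_meth)) /
                 sum(as.numeric(n_total)), n_sites = .N), by = region]
  out <- merge(reg, lv, by = "region")
  setorderv(out, c("chrom", "start"))
  out[, id := paste0("hmr_", seq_len(.N))]
  out[, region := NULL]
  setcolorder(out, c("id", "chrom", "start", "end", "mean_level",
                     "n_windows", "n_sites"))
  out[]
}
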