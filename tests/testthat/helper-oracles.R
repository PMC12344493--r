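## Independent oracles and small fixture builders used across tests.
## These deliberately use naive loops / closed forms, never the
## package's own code paths.

## quick site-table builder
sites_of <- function(chrom, pos, strand = "+", n_meth, n_total,
                     dinuc = NA, trinuc = NA) {
  methyl_sites(chrom = chrom, pos = pos, strand = strand,
               dinuc = dinuc, trinuc = trinuc,
               n_meth = n_meth, n_total = n_total)
}

## random sparse site table on one chromosome (CX-style, no contexts)
random_sites <- function(chrom, len, n, depth = 20) {
  pos <- sort(sample.int(len, min(n, len)) - 1L)
  tot <- rpois(length(pos), depth) + 1L
  p <- ifelse(runif(length(pos)) < 0.3, runif(length(pos), 0.3, 1), 0.01)
  sites_of(chrom, pos, sample(c("+", "-"), length(pos), TRUE),
           rbinom(length(pos), tot, p), tot)
}

## --- brute-force hypermethylated-region caller -----------------------
## enumerate every window, filter, merge by interval union
oracle_hmr <- function(sites, genome_lengths, window, step, min_level,
                       min_sites) {
  out <- list()
  for (ch in names(genome_lengths)) {
    len <- genome_lengths[[ch]]
    x <- sites[sites$chrom == ch & sites$n_total > 0, ]
    kept <- NULL
    k <- 0L
    while (k * step < len) {
      ws <- k * step; we <- min(ws + window, len)
      inw <- x$pos >= ws & x$pos < we
      t <- sum(x$n_total[inw]); m <- sum(x$n_meth[inw])
      if (sum(inw) >= min_sites && t > 0 && m / t > min_level)
        kept <- rbind(kept, data.frame(s = ws, e = we))
      k <- k + 1L
    }
    if (is.null(kept)) next
    kept <- kept[order(kept$s), ]
    cur_s <- kept$s[1]; cur_e <- kept$e[1]
    for (i in seq_len(nrow(kept))[-1]) {
      if (kept$s[i] <= cur_e) cur_e <- max(cur_e, kept$e[i])
      else {
        out[[length(out) + 1]] <- data.frame(chrom = ch, start = cur_s,
                                             end = cur_e)
        cur_s <- kept$s[i]; cur_e <- kept$e[i]
      }
    }
    out[[length(out) + 1]] <- data.frame(chrom = ch, start = cur_s,
                                         end = cur_e)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  do.call(rbind, out)
}

## --- exhaustive two-sided Fisher p via lchoose ------------------------
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d; r <- a + b; cc <- a + c
  if (r == 0 || cc == 0 || r == n || cc == n) return(1)
  ks <- max(0, r + cc - n):min(r, cc)
  logp <- lchoose(cc, ks) + lchoose(n - cc, r - ks) - lchoose(n, r)
  p <- exp(logp)
  obs <- p[ks == a]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

## --- exhaustive Dollo: minimum-loss single-gain assignment ------------
## enumerates every internal-state vector; returns min losses and the
## (unique) argmin states
oracle_dollo <- function(tree, present_tips) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  nnode <- ntip + nint
  E <- tree$edge
  leaf <- logical(ntip); leaf[present_tips] <- TRUE
  best <- Inf; best_states <- NULL
  for (mask in 0:(2^nint - 1)) {
    st <- c(leaf, as.logical(bitwAnd(mask, 2^(0:(nint - 1)))))
    gains <- sum(!st[E[, 1]] & st[E[, 2]]) + st[ntip + 1L]
    if (gains != 1) next
    losses <- sum(st[E[, 1]] & !st[E[, 2]])
    if (losses < best) { best <- losses; best_states <- st }
  }
  list(n_losses = best, states = best_states)
}

## --- naive metaprofile: per-site loop -------------------------------
oracle_metaprofile <- function(sites, feats, body_bins, flank_bp,
                               flank_bins) {
  nb <- 2 * flank_bins + body_bins
  m <- t <- numeric(nb)
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    for (j in seq_len(nrow(sites))) {
      sdt <- sites[j, ]
      if (sdt$chrom != f$chrom || sdt$n_total < 1) next
      p <- sdt$pos
      bin <- NA
      if (p >= f$start - flank_bp && p < f$start)
        bin <- floor((p - (f$start - flank_bp)) / flank_bp * flank_bins)
      else if (p >= f$start && p < f$end)
        bin <- flank_bins +
          floor((p - f$start) / (f$end - f$start) * body_bins)
      else if (p >= f$end && p < f$end + flank_bp)
        bin <- flank_bins + body_bins +
          floor((p - f$end) / flank_bp * flank_bins)
      if (is.na(bin)) next
      bin <- min(bin, nb - 1)
      if (f$strand == "-") bin <- nb - 1 - bin
      m[bin + 1] <- m[bin + 1] + sdt$n_meth
      t[bin + 1] <- t[bin + 1] + sdt$n_total
    }
  }
  ifelse(t > 0, m / t, NA_real_)
}

## --- K2P under the true substitution process -------------------------
## evolve a sequence for distance d_true with transition/transversion
## rate ratio kappa = alpha/beta, using the exact K2P site
## probabilities, so the K2P estimator is consistent
evolve_k2p <- function(consensus, d_true, kappa = 4) {
  ## d = (alpha + 2 beta) t ; set beta t = d / (kappa + 2)
  bt <- d_true / (kappa + 2); at <- kappa * bt
  P <- 0.25 - 0.5 * exp(-2 * (at + bt)) + 0.25 * exp(-4 * bt)
  Q <- 0.5 - 0.5 * exp(-4 * bt)
  TS <- c(A = "G", G = "A", C = "T", T = "C")
  TV <- list(A = c("C", "T"), G = c("C", "T"),
             C = c("A", "G"), T = c("A", "G"))
  x <- strsplit(consensus, "")[[1]]
  u <- runif(length(x))
  out <- x
  ts <- u < P; tv <- u >= P & u < P + Q
  out[ts] <- TS[x[ts]]
  out[tv] <- vapply(x[tv], function(b) sample(TV[[b]], 1), "")
  paste(out, collapse = "")
}

## --- greedy viral chaining, naive re-implementation -------------------
oracle_chains <- function(genes_dt, viral_ids, max_gap_genes,
                          max_gap_bp, min_genes) {
  g <- genes_dt[order(genes_dt$chrom, genes_dt$start), ]
  res <- list()
  for (ch in unique(g$chrom)) {
    gg <- g[g$chrom == ch, ]
    vidx <- which(gg$id %in% viral_ids)
    if (!length(vidx)) next
    chain <- list(vidx[1])
    for (i in seq_along(vidx)[-1]) {
      prev <- chain[[length(chain)]]
      last <- prev[length(prev)]
      if (vidx[i] - last - 1 <= max_gap_genes &&
          gg$start[vidx[i]] - gg$end[last] <= max_gap_bp)
        chain[[length(chain)]] <- c(prev, vidx[i])
      else chain[[length(chain) + 1]] <- vidx[i]
    }
    for (cc in chain)
      if (length(cc) >= min_genes)
        res[[length(res) + 1]] <-
          data.frame(chrom = ch, start = min(gg$start[cc]),
                     end = max(gg$end[cc]), n_viral = length(cc))
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_viral = integer()))
  do.call(rbind, res)
}

## write a hit-table data.table to a temp file, return path
write_hits_tmp <- function(hits_raw) {
  tf <- tempfile(fileext = ".tsv")
  data.table::fwrite(hits_raw, tf, sep = "\t", quote = FALSE)
  tf
}

## node A is inside the clade rooted at B?
in_clade <- function(tree, node, clade_root) {
  ntip <- length(tree$tip.label)
  if (node == clade_root) return(TRUE)
  par <- node
  repeat {
    e <- tree$edge[tree$edge[, 2] == par, 1]
    if (!length(e)) return(FALSE)
    if (e == clade_root) return(TRUE)
    par <- e
  }
}

## one-family presence matrix on a tree
mk_profile <- function(tree, present, fam = "f1") {
  m <- matrix("absent", length(tree$tip.label), 1,
              dimnames = list(tree$tip.label, fam))
  m[present, 1] <- "present"
  m
}
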