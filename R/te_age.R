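#' Construct a consensus-vs-insertion alignment
#'
#' @param te_id insertion identifier (matches the feature/summary id).
#' @param family TE family label.
#' @param consensus,insertion aligned sequences of equal length over
#'   the alphabet A, C, G, T, N, "-" (gap).
#' @param feature optional genomic feature row for the insertion.
#' @return object of class `insertion_alignment`.
#' @export
insertion_alignment <- function(te_id, family, consensus, insertion,
                                feature = NULL) {
  consensus <- toupper(consensus); insertion <- toupper(insertion)
  if (nchar(consensus) != nchar(insertion))
    stop("aligned sequences must have equal length")
  ok <- function(s) grepl("^[ACGTN-]*$", s)
  if (!ok(consensus) || !ok(insertion))
    stop("alignment alphabet is A, C, G, T, N, -")
  structure(list(te_id = te_id, family = family,
                 consensus = consensus, insertion = insertion,
                 feature = feature),
            class = "insertion_alignment")
}

#' Kimura 2-parameter divergence with optional CpG-modified weighting
#'
#' Over the comparable columns (both bases in A/C/G/T), P is the
#' transition proportion and Q the transversion proportion;
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`. With
#' `cpg_modified = TRUE`, a transition whose consensus column belongs
#' to a CpG dinucleotide of the (ungapped) consensus contributes only
#' `cpg_weight` (default 1/10) of a transition — the divCpGMod-style
#' discount for hypermutable methylated CpGs; both members of the CpG
#' are discounted. The alternative convention of ignoring CpG
#' transitions entirely corresponds to `cpg_weight = 0`.
#'
#' @param aln an [insertion_alignment()].
#' @param cpg_modified apply the CpG discount (default TRUE).
#' @param cpg_weight weight of a CpG transition (default 0.1).
#' @return object of class `k2p_result`: P, Q, d, n_compared,
#'   cpg_modified, saturated (TRUE and d = NA when the logarithm's
#'   argument is non-positive).
#' @export
kimura2p <- function(aln, cpg_modified = TRUE, cpg_weight = 0.1) {
  a <- strsplit(aln$consensus, "", fixed = TRUE)[[1]]
  b <- strsplit(aln$insertion, "", fixed = TRUE)[[1]]
  real <- c("A", "C", "G", "T")
  comparable <- a %in% real & b %in% real
  n <- sum(comparable)
  if (n == 0L) stop("no comparable (non-gap, non-N) columns")
  mism <- comparable & a != b
  transition <- mism & ((a == "A" & b == "G") | (a == "G" & b == "A") |
                          (a == "C" & b == "T") | (a == "T" & b == "C"))
  transversion <- mism & !transition

  cpg_col <- rep(FALSE, length(a))
  if (cpg_modified) {
    ug <- which(a != "-")                     # columns with consensus base
    u <- a[ug]
    is_c <- u == "C" & c(u[-1], "") == "G"    # C of a consensus CpG
    cpg_ug <- is_c | c(FALSE, is_c[-length(is_c)])  # ...and its G
    cpg_col[ug] <- cpg_ug
  }
  w <- ifelse(cpg_col & cpg_modified, cpg_weight, 1)
  P <- sum(w[transition]) / n
  Q <- sum(transversion) / n
  arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
  saturated <- arg1 <= 0 || arg2 <= 0
  d <- if (saturated) NA_real_ else -0.5 * log(arg1 * sqrt(arg2))
  structure(list(P = P, Q = Q, d = d, n_compared = n,
                 cpg_modified = cpg_modified, saturated = saturated),
            class = "k2p_result")
}

#' Read consensus-vs-insertion alignments (simplified dialect)
#'
#' Plain-text blocks, one per insertion:
#' \preformatted{
#' >te_id <TAB> family
#' ALIGNED-CONSENSUS
#' ALIGNED-INSERTION
#' }
#' Blank lines between blocks are ignored.
#'
#' @param path alignment file.
#' @return list of [insertion_alignment()] objects.
#' @export
read_insertion_alignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) return(list())
  if (any(diff(c(hdr, length(lines) + 1L)) != 3L))
    stop("malformed alignment file: each '>' header needs exactly ",
         "two sequence lines")
  lapply(hdr, function(i) {
    fields <- strsplit(sub("^>", "", lines[i]), "\t", fixed = TRUE)[[1]]
    insertion_alignment(te_id = fields[1],
                        family = if (length(fields) > 1) fields[2]
                                 else NA_character_,
                        consensus = lines[i + 1L],
                        insertion = lines[i + 2L])
  })
}

#' Tabulate K2P results
#'
#' @param k2p_list list of `k2p_result` objects or of
#'   `insertion_alignment` objects (computed on the fly).
#' @param alns alignments providing te_id/family when `k2p_list`
#'   contains results (same order); ignored otherwise.
#' @param ... passed to [kimura2p()] when computing.
#' @return `data.table`: te_id, family, P, Q, d, n_compared, saturated.
#' @export
k2p_table <- function(k2p_list, alns = NULL, ...) {
  if (length(k2p_list) && inherits(k2p_list[[1]], "insertion_alignment")) {
    alns <- k2p_list
    k2p_list <- lapply(alns, kimura2p, ...)
  }
  rbindlist(mapply(function(r, a) {
    data.table(te_id = a$te_id, family = a$family, P = r$P, Q = r$Q,
               d = r$d, n_compared = r$n_compared,
               saturated = r$saturated)
  }, k2p_list, alns, SIMPLIFY = FALSE))
}

#' Methylation level by TE age bin
#'
#' Joins per-insertion divergence estimates with per-insertion
#' methylation summaries and pools read counts per family and age bin.
#' Saturated insertions (undefined d) land in a "saturated" overflow
#' bin.
#'
#' @param k2p `data.table` from [k2p_table()].
#' @param te_summaries [summarize_features()] output for the same
#'   insertions (feature_id = te_id).
#' @param age_bins increasing breakpoints for d; values beyond the last
#'   break go to an overflow bin.
#' @return `data.table`: family, age_bin, n_insertions, level,
#'   n_meth_reads, n_total_reads.
#' @export
age_methylation_profile <- function(k2p, te_summaries,
                                    age_bins = c(0, 0.05, 0.1, 0.2, 0.4)) {
  if (is.unsorted(age_bins, strictly = TRUE))
    stop("age_bins must be strictly increasing")
  x <- merge(as.data.table(te_summaries), as.data.table(k2p),
             by.x = "feature_id", by.y = "te_id")
  brk <- c(age_bins, Inf)
  lab <- c(paste0("[", head(brk, -1), ",",
                  ifelse(is.finite(tail(brk, -1)), tail(brk, -1), "Inf"),
                  ")"))
  x[, age_bin := ifelse(is.na(d), "saturated",
                        as.character(cut(d, breaks = brk, labels = lab,
                                         right = FALSE,
                                         include.lowest = FALSE)))]
  out <- x[, .(n_insertions = .N,
               level = {
                 t <- sum(as.numeric(n_total_reads))
                 if (t > 0) sum(as.numeric(n_meth_reads)) / t else NA_real_
               },
               n_meth_reads = sum(as.numeric(n_meth_reads)),
               n_total_reads = sum(as.numeric(n_total_reads))),
           by = .(family, age_bin)]
  setorderv(out, c("family", "age_bin"))
  out[]
}
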