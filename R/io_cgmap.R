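#' Read per-cytosine methylation calls in CGmap format
#'
#' CGmap is the 8-column TSV emitted by CGmapTools: (1) chrom,
#' (2) Watson-strand base C|G, (3) 1-based position, (4) trinucleotide
#' context (CG/CHG/CHH), (5) dinucleotide context (CA/CC/CG/CT),
#' (6) methylation level, (7) methylated read count, (8) total read
#' count. Column 6 is ignored: levels are always recomputed from the
#' counts, which are the primitive data. Positions are converted to
#' 0-based and strand is derived from column 2 (C = "+", G = "-").
#'
#' @param path CGmap file (plain text, tab separated).
#' @param genome optional genome (FASTA path or DNAStringSet). When
#'   supplied, contexts are recomputed from the sequence; stored
#'   contexts that disagree are flagged in a logical
#'   `context_mismatch` column and a warning summarises the count.
#' @param min_cov drop sites with total coverage below this (default 0:
#'   keep everything).
#' @return a site table (see [methyl_sites()]); with `genome`, an extra
#'   `context_mismatch` column.
#' @export
read_cgmap <- function(path, genome = NULL, min_cov = 0L) {
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = "character", quote = "")
  if (nrow(dt) == 0L)
    return(methyl_sites(character(), integer(), character(),
                        n_meth = integer(), n_total = integer()))
  if (ncol(dt) != 8L)
    stop("CGmap parse error: expected 8 tab-separated columns, found ",
         ncol(dt), " in ", path)
  short <- which(is.na(dt[[8]]) | dt[[8]] == "")
  if (length(short))
    stop("CGmap parse error at line ", short[1], ": wrong column count")
  badb <- which(!dt[[2]] %in% c("C", "G"))
  if (length(badb))
    stop("CGmap parse error at line ", badb[1],
         ": unknown Watson base '", dt[[2]][badb[1]], "'")
  pos1 <- suppressWarnings(as.integer(dt[[3]]))
  nm <- suppressWarnings(as.integer(dt[[7]]))
  nt <- suppressWarnings(as.integer(dt[[8]]))
  badi <- which(is.na(pos1) | is.na(nm) | is.na(nt) |
                  as.character(nm) != dt[[7]] | as.character(nt) != dt[[8]])
  if (length(badi))
    stop("CGmap parse error at line ", badi[1],
         ": non-integer position or counts")
  badc <- which(nm > nt | nm < 0L | nt < 0L)
  if (length(badc))
    stop("CGmap parse error at line ", badc[1],
         ": methylated count exceeds total count")
  tri <- dt[[4]]; tri[!tri %in% c("CG", "CHG", "CHH")] <- NA_character_
  di <- dt[[5]]; di[!di %in% c("CA", "CC", "CG", "CT")] <- NA_character_
  sites <- data.table(
    chrom = dt[[1]], pos = pos1 - 1L,
    strand = ifelse(dt[[2]] == "C", "+", "-"),
    dinuc = di, trinuc = tri, n_meth = nm, n_total = nt
  )
  if (min_cov > 0L) sites <- sites[n_total >= min_cov]
  validate_sites(sites)
  if (!is.null(genome)) {
    ctx <- classify_context(genome, sites$chrom, sites$pos, sites$strand)
    mism <- (!is.na(sites$dinuc) & !is.na(ctx$dinuc) &
               sites$dinuc != ctx$dinuc) |
            (!is.na(sites$trinuc) & !is.na(ctx$trinuc) &
               sites$trinuc != ctx$trinuc)
    sites[, `:=`(dinuc = ctx$dinuc, trinuc = ctx$trinuc,
                 context_mismatch = mism)]
    if (any(mism))
      warning(sum(mism), " site(s) had stored contexts disagreeing ",
              "with the genome sequence; recomputed values kept")
  }
  sites[]
}

#' Write a site table as CGmap
#'
#' Inverse of [read_cgmap()]: positions go back to 1-based, strand to
#' the Watson base, NA contexts to "--", and column 6 is the level
#' recomputed from counts ("na" for uncovered sites). Reading a written
#' file returns the identical site table.
#'
#' @param sites site table.
#' @param path output file.
#' @export
write_cgmap <- function(sites, path) {
  validate_sites(sites)
  lev <- ifelse(sites$n_total > 0,
                formatC(sites$n_meth / sites$n_total, digits = 6,
                        format = "g"),
                "na")
  out <- data.table(
    sites$chrom,
    ifelse(sites$strand == "+", "C", "G"),
    sites$pos + 1L,
    ifelse(is.na(sites$trinuc), "--", sites$trinuc),
    ifelse(is.na(sites$dinuc), "--", sites$dinuc),
    lev, sites$n_meth, sites$n_total
  )
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
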