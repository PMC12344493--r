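#' Read genomic features from GFF3 or BED
#'
#' Both formats are converted to the internal 0-based half-open
#' convention: BED is already 0-based half-open; GFF3 is 1-based closed
#' and is shifted at the boundary. GFF3 features are keyed by their
#' `ID` attribute (falling back to `Name`); a `class` attribute, when
#' present, populates `class_label` (used for TE families).
#'
#' @param path annotation file.
#' @param format "gff3", "bed", or "auto" (by extension).
#' @param kind value for the `kind` column ("gene", "TE", ...).
#' @param feature_types for GFF3, keep only these `type` values
#'   (default NULL: keep all records).
#' @return a feature table (see [features()]).
#' @export
read_features <- function(path, format = c("auto", "gff3", "bed"),
                          kind = "gene", feature_types = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3"
              else if (ext == "bed") "bed"
              else stop("cannot guess format from extension: ", path)
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3"
                                           else "bed")
  mc <- as.data.frame(GenomicRanges::mcols(gr))
  if (format == "gff3" && !is.null(feature_types) && "type" %in% names(mc))
    { keep <- mc$type %in% feature_types; gr <- gr[keep]; mc <- mc[keep, , drop = FALSE] }
  ids <- if (format == "bed" && "name" %in% names(mc)) as.character(mc$name)
         else if ("ID" %in% names(mc)) as.character(mc$ID)
         else if ("Name" %in% names(mc)) as.character(mc$Name)
         else rep(NA_character_, length(gr))
  miss <- is.na(ids) | ids == ""
  if (any(miss)) ids[miss] <- paste0(kind, "_", which(miss))
  cls <- if ("class" %in% names(mc)) as.character(mc$class)
         else NA_character_
  feats <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # GRanges is 1-based closed
    end = GenomicRanges::end(gr),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    id = ids, kind = kind, class_label = cls
  )
  validate_features(feats)
  feats[]
}

#' Write features (or regions) as BED6
#'
#' @param feats feature table; a `score` column, when present, fills
#'   BED column 5 (otherwise 0).
#' @param path output file.
#' @export
write_bed <- function(feats, path) {
  score <- if ("score" %in% names(feats)) feats$score else 0L
  strand <- if ("strand" %in% names(feats)) feats$strand else "."
  out <- data.table(feats$chrom, feats$start, feats$end, feats$id,
                    score, ifelse(strand == ".", ".", strand))
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write features as GFF3
#'
#' @param feats feature table.
#' @param path output file.
#' @param source value of GFF3 column 2.
#' @param type value of GFF3 column 3 (defaults to the `kind` column).
#' @export
write_gff3 <- function(feats, path, source = "methylgate", type = NULL) {
  type <- if (is.null(type)) feats$kind else rep(type, nrow(feats))
  attr_col <- paste0("ID=", feats$id,
                     ifelse(is.na(feats$class_label), "",
                            paste0(";class=", feats$class_label)))
  out <- data.table(feats$chrom, source, type,
                    feats$start + 1L, feats$end, ".",
                    ifelse(feats$strand == ".", ".", feats$strand),
                    ".", attr_col)
  writeLines("##gff-version 3", path)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
         append = TRUE)
  invisible(path)
}

#' Export per-site methylation levels as bedGraph
#'
#' One line per covered cytosine passing the context filter; the score
#' is the per-site level from counts.
#'
#' @param sites site table.
#' @param path output file.
#' @param context_mode see [context_filter()].
#' @param min_cov minimum coverage per site.
#' @export
write_bedgraph <- function(sites, path, context_mode = "CX",
                           min_cov = 1L) {
  keep <- context_filter(sites, context_mode) & sites$n_total >= min_cov
  x <- sites[keep]
  out <- data.table(x$chrom, x$pos, x$pos + 1L,
                    round(x$n_meth / x$n_total, 6))
  data.table::setorderv(out, c("V1", "V2"))
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
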