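#' Classify the sequence context of cytosines
#'
#' For a cytosine at `pos` (0-based) on `strand`, the dinucleotide
#' context is C followed by the next base on the same strand
#' (CA/CC/CG/CT) and the trinucleotide context is CG when the next base
#' is G, otherwise CHG when the base after next is G, otherwise CHH
#' (H = A, C or T). Contexts are NA when the required window runs off
#' the contig or contains an ambiguous base.
#'
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param chrom,pos,strand parallel vectors locating the cytosines;
#'   `pos` is 0-based. On "-" the Watson base at `pos` must be G.
#' @return list with character vectors `dinuc` and `trinuc`.
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  genome <- as_genome(genome)
  chrom <- as.character(chrom); pos <- as.integer(pos)
  strand <- as.character(strand)
  n <- length(pos)
  stopifnot(length(chrom) == n, length(strand) == n)
  dinuc <- rep(NA_character_, n); trinuc <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome)) stop("contig not in genome: ", ch)
    s <- strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1]]
    idx <- which(chrom == ch)
    res <- context_from_chars(s, pos[idx], strand[idx], ch)
    dinuc[idx] <- res$dinuc; trinuc[idx] <- res$trinuc
  }
  list(dinuc = dinuc, trinuc = trinuc)
}

## core context logic on a character vector of one contig
context_from_chars <- function(s, pos, strand, chrom_name = "?") {
  L <- length(s)
  if (any(pos < 0L | pos >= L))
    stop("position out of range on ", chrom_name)
  base <- s[pos + 1L]
  plus <- strand == "+"
  bad <- (plus & base != "C") | (!plus & base != "G")
  if (any(bad))
    stop("base at position ", pos[which(bad)[1]], " on ", chrom_name,
         " is not C on strand ", strand[which(bad)[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  at <- function(i) ifelse(i >= 1L & i <= L, s[pmax(i, 1L)], NA_character_)
  b1 <- ifelse(plus, at(pos + 2L), unname(comp[at(pos)]))
  b2 <- ifelse(plus, at(pos + 3L), unname(comp[at(pos - 1L)]))
  ok1 <- !is.na(b1) & b1 %in% c("A", "C", "G", "T")
  ok2 <- !is.na(b2) & b2 %in% c("A", "C", "G", "T")
  dinuc <- ifelse(ok1, paste0("C", b1), NA_character_)
  trinuc <- rep(NA_character_, length(pos))
  trinuc[ok1 & b1 == "G"] <- "CG"
  h1 <- ok1 & b1 != "G"
  trinuc[h1 & ok2 & b2 == "G"] <- "CHG"
  trinuc[h1 & ok2 & b2 != "G"] <- "CHH"
  list(dinuc = dinuc, trinuc = trinuc)
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome) && !is.null(names(genome)))
    return(Biostrings::DNAStringSet(genome))
  stop("genome must be a DNAStringSet, a named character vector, ",
       "or a FASTA path")
}
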