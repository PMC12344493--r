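#' Read a per-gene best-hit table with taxonomy
#'
#' Expects a TSV with header columns `gene_id`, `taxonomy`, `bitscore`
#' and optionally `evalue`, as produced by annotating a best-hit search
#' against a comprehensive protein database with resolved taxonomy.
#' The `taxonomy` string is a semicolon-separated lineage from
#' superkingdom down to genus (e.g.
#' "Eukaryota;Amoebozoa;...;Acanthamoeba").
#'
#' Per gene, hits whose genus equals `self_genus` are discarded (to
#' remove trivial self-matches) and at most `max_hits` best-scoring
#' records are retained. Records whose lineage lacks a recognisable
#' superkingdom (Eukaryota, Bacteria, Archaea, Viruses) are skipped
#' with a warning, never fatally.
#'
#' @param path hit table TSV.
#' @param self_genus genus of the query species.
#' @param max_hits cap per gene (default 10).
#' @return `data.table` with columns gene_id, superkingdom, genus,
#'   lineage, bitscore, evalue; zero-hit genes are simply absent.
#' @export
read_hit_table <- function(path, self_genus, max_hits = 10L) {
  dt <- fread(path, header = TRUE, sep = "\t", quote = "")
  if (nrow(dt) == 0L)
    return(data.table(gene_id = character(), superkingdom = character(),
                      genus = character(), lineage = character(),
                      bitscore = numeric(), evalue = numeric()))
  need <- c("gene_id", "taxonomy", "bitscore")
  if (!all(need %in% names(dt)))
    stop("hit table must have columns: ", paste(need, collapse = ", "))
  if (!"evalue" %in% names(dt)) dt[, evalue := NA_real_]
  parts <- strsplit(dt$taxonomy, ";", fixed = TRUE)
  parts <- lapply(parts, function(p) trimws(p[p != ""]))
  sk <- vapply(parts, function(p) {
    hit <- p[p %in% c("Eukaryota", "Bacteria", "Archaea", "Viruses")]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  gen <- vapply(parts, function(p) {
    if (length(p)) p[length(p)] else NA_character_
  }, character(1))
  bad <- is.na(sk) | is.na(gen)
  if (any(bad))
    warning(sum(bad), " hit record(s) with unparseable taxonomy skipped")
  hits <- data.table(
    gene_id = as.character(dt$gene_id)[!bad],
    superkingdom = sk[!bad], genus = gen[!bad],
    lineage = dt$taxonomy[!bad],
    bitscore = as.numeric(dt$bitscore)[!bad],
    evalue = as.numeric(dt$evalue)[!bad]
  )
  hits <- hits[genus != self_genus]
  setorder(hits, gene_id, -bitscore)
  hits <- hits[, head(.SD, max_hits), by = gene_id]
  hits[]
}
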