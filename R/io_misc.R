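#' Read a species-by-family presence/absence matrix
#'
#' TSV with a `species` first column and one column per gene family.
#' Cell encoding: `1` present, `0` absent, `?` potential presence
#' (evidence with atypical domain architecture or weak support).
#'
#' @param path matrix TSV.
#' @return character matrix (species rows, family columns) with values
#'   "present", "absent", "potential".
#' @export
read_presence_matrix <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t", colClasses = "character")
  if (names(dt)[1] != "species")
    stop("presence matrix must have a first column named 'species'")
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt$species
  bad <- !m %in% c("1", "0", "?")
  if (any(bad)) stop("presence matrix cells must be 1, 0 or ?")
  out <- matrix(NA_character_, nrow(m), ncol(m),
                dimnames = dimnames(m))
  out[m == "1"] <- "present"
  out[m == "0"] <- "absent"
  out[m == "?"] <- "potential"
  out
}

#' @rdname read_presence_matrix
#' @param m matrix as returned by `read_presence_matrix`.
#' @export
write_presence_matrix <- function(m, path) {
  enc <- matrix("0", nrow(m), ncol(m))
  enc[m == "present"] <- "1"
  enc[m == "potential"] <- "?"
  dt <- data.table(species = rownames(m))
  for (j in seq_len(ncol(m))) set(dt, j = colnames(m)[j], value = enc[, j])
  fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a rooted species tree in newick format
#'
#' Thin wrapper over [ape::read.tree()] that enforces rootedness and
#' unique tip labels, the preconditions of Dollo reconstruction.
#'
#' @param path newick file.
#' @return an `ape` `phylo` object.
#' @export
read_species_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick tree: ", path)
  if (!ape::is.rooted(tr)) stop("species tree must be rooted")
  if (anyDuplicated(tr$tip.label)) stop("tree tip labels must be unique")
  tr
}
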