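#' Dollo parsimony reconstruction of ancestral gene-family content
#'
#' Under Dollo parsimony each family is gained exactly once and may be
#' lost any number of times. The gain node is therefore the most
#' recent common ancestor (MRCA) of all leaves carrying the family; a
#' node is ancestrally present iff it lies on a path from the gain
#' node to a present leaf; the losses are the maximal absent subtrees
#' below the gain node. This is the unique minimum-loss single-gain
#' assignment.
#'
#' "Potential" presences (ambiguous evidence) are collapsed by
#' `treat_potential_as` before reconstruction; comparing both
#' treatments brackets the answer (treating them as absent can never
#' yield more ancestral presences than treating them as present).
#'
#' @param tree rooted `phylo` tree (polytomies allowed); every species
#'   in the profile must be a tip label.
#' @param profile character matrix species x family with values
#'   "present", "absent", "potential" (see
#'   [read_presence_matrix()]), or a 0/1 numeric matrix.
#' @param treat_potential_as "present" (default) or "absent".
#' @return object of class `dollo_reconstruction`: list with `tree`
#'   and per-family entries `families[[f]]` holding `gain_node`
#'   (ape node id), `states` (logical per node, tips then internals),
#'   `loss_nodes` (child node of each loss branch) and `n_losses`.
#' @export
dollo_reconstruct <- function(tree, profile,
                              treat_potential_as = c("present",
                                                     "absent")) {
  treat_potential_as <- match.arg(treat_potential_as)
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.numeric(profile)) {
    profile <- ifelse(profile > 0, "present", "absent")
  }
  unknown <- setdiff(rownames(profile), tree$tip.label)
  if (length(unknown))
    stop("species in matrix not in tree: ",
         paste(unknown, collapse = ", "))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  po <- postorder_nodes(tree)

  fams <- colnames(profile)
  out <- vector("list", length(fams)); names(out) <- fams
  for (f in fams) {
    st <- profile[, f]
    pres_sp <- rownames(profile)[st == "present" |
                                   (st == "potential" &
                                      treat_potential_as == "present")]
    if (!length(pres_sp))
      stop("family absent everywhere under this treatment: ", f)
    tips <- match(pres_sp, tree$tip.label)
    ## leaf counts of present descendants, postorder
    npres <- integer(nnode)
    npres[tips] <- 1L
    for (nd in po)
      npres[nd] <- sum(npres[kids[[as.character(nd)]]])
    gain <- if (length(tips) == 1L) tips else mrca_node(tree, tips, npres)
    ## states: in clade(gain) and >=1 present descendant leaf
    inclade <- logical(nnode); inclade[gain] <- TRUE
    for (nd in rev(po))                    # preorder over internals
      if (inclade[nd])
        for (k in kids[[as.character(nd)]]) inclade[k] <- TRUE
    states <- inclade & npres > 0L
    loss_nodes <- tree$edge[, 2][states[tree$edge[, 1]] &
                                   inclade[tree$edge[, 2]] &
                                   npres[tree$edge[, 2]] == 0L]
    out[[f]] <- list(gain_node = gain, states = states,
                     loss_nodes = sort(loss_nodes),
                     n_losses = length(loss_nodes))
  }
  structure(list(tree = tree, families = out,
                 treat_potential_as = treat_potential_as),
            class = "dollo_reconstruction")
}

## internal-node ids in postorder (children before parents)
postorder_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  re <- ape::reorder.phylo(tree, "postorder")
  unique(re$edge[, 1])
}

## MRCA via the present-descendant counts already computed: the
## deepest node (away from root) whose clade holds all present tips
mrca_node <- function(tree, tips, npres) {
  total <- length(tips)
  ntip <- length(tree$tip.label)
  cand <- which(npres == total)
  ## among candidates, the one that is a descendant of all others:
  ## walk down from the root choosing the child containing all tips
  root <- ntip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  node <- root
  repeat {
    ch <- kids[[as.character(node)]]
    nxt <- ch[!is.na(ch) & npres[ch] == total]
    if (length(nxt) == 0L) return(node)
    node <- nxt[1]
    if (node <= ntip) return(node)
  }
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  nf <- length(x$families)
  nl <- vapply(x$families, `[[`, integer(1), "n_losses")
  cat(sprintf(
    "Dollo reconstruction: %d families on %d tips (potential = %s)\n",
    nf, length(x$tree$tip.label), x$treat_potential_as))
  cat(sprintf("  losses per family: median %g, max %g\n",
              stats::median(nl), max(nl)))
  invisible(x)
}

#' Ancestral repertoire at a node, plus per-species substrate summary
#'
#' @param recon a [dollo_reconstruct()] result.
#' @param node node of interest: an ape node id, `"root"`, a tip
#'   label, or an internal node label when the tree carries them.
#' @param substrate_map optional named character vector family ->
#'   substrate (e.g. "DNA"/"RNA"); when given, the report counts the
#'   species possessing no family with substrate "DNA".
#' @return list: `node`, `families` present at the node,
#'   `species_without_dna` (NULL without a map).
#' @export
repertoire_report <- function(recon, node = "root",
                              substrate_map = NULL) {
  tree <- recon$tree
  ntip <- length(tree$tip.label)
  nid <- resolve_node(tree, node)
  fams <- names(recon$families)[vapply(recon$families, function(fr)
    fr$states[nid], logical(1))]
  species_without_dna <- NULL
  if (!is.null(substrate_map)) {
    dna_fams <- names(substrate_map)[substrate_map == "DNA"]
    has <- vapply(seq_len(ntip), function(tp)
      any(vapply(recon$families[intersect(names(recon$families),
                                          dna_fams)],
                 function(fr) fr$states[tp], logical(1))),
      logical(1))
    species_without_dna <- tree$tip.label[!has]
  }
  list(node = nid, families = fams,
       species_without_dna = species_without_dna)
}

resolve_node <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (is.numeric(node)) {
    nid <- as.integer(node)
    if (nid < 1L || nid > ntip + tree$Nnode) stop("unknown node: ", node)
    return(nid)
  }
  if (identical(node, "root")) return(ntip + 1L)
  hit <- match(node, tree$tip.label)
  if (!is.na(hit)) return(hit)
  if (!is.null(tree$node.label)) {
    hit <- match(node, tree$node.label)
    if (!is.na(hit)) return(ntip + hit)
  }
  stop("unknown node: ", node)
}
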