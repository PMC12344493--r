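#' Simulate phyletic profiles with known gain/loss history
#'
#' A random rooted tree is drawn, each gene family is gained at one
#' random node and then lost independently along each descendant
#' branch with probability `loss_rate` (everything below a loss stays
#' absent). The observed matrix holds the resulting leaf states;
#' families extinct in every leaf are resampled, never emitted. The
#' recorded truth is sufficient to score a Dollo reconstruction: with
#' no homoplasy the Dollo gain node can never be tipward of the true
#' gain node, and with `loss_rate = 0` it recovers it exactly.
#'
#' @param seed integer seed.
#' @param n_species number of leaves.
#' @param n_families number of families.
#' @param loss_rate per-branch loss probability in \[0, 1).
#' @return list: `tree` (rooted phylo, tips "sp01"...), `matrix`
#'   (species x family, "present"/"absent"), `truth` (`data.table`
#'   with family, gain_node, loss_nodes list-column, n_losses).
#' @export
simulate_profiles <- function(seed, n_species = 12L, n_families = 200L,
                              loss_rate = 0.2) {
  if (loss_rate < 0 || loss_rate >= 1)
    stop("loss_rate must be in [0, 1)")
  set.seed(phase_seed(seed, 7L))
  tree <- ape::rtree(n_species, rooted = TRUE,
                     tip.label = sprintf("sp%02d", seq_len(n_species)))
  ntip <- n_species
  nnode <- ntip + tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  po <- postorder_nodes(tree)
  pre <- rev(po)

  m <- matrix("absent", ntip, n_families,
              dimnames = list(tree$tip.label,
                              sprintf("fam%04d", seq_len(n_families))))
  truth <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    repeat {
      gain <- sample.int(nnode, 1)
      state <- logical(nnode); state[gain] <- TRUE
      losses <- integer()
      for (nd in pre) {
        if (!state[nd]) next
        for (k in kids[[as.character(nd)]]) {
          if (runif(1) < loss_rate) losses <- c(losses, k)
          else state[k] <- TRUE
        }
      }
      ## losses below other losses are unreachable; keep only those
      ## whose parent is present (maximal absent subtrees)
      leaf_states <- state[seq_len(ntip)]
      if (any(leaf_states)) {
        m[leaf_states, f] <- "present"
        truth[[f]] <- data.table(
          family = colnames(m)[f], gain_node = gain,
          loss_nodes = list(sort(losses)), n_losses = length(losses))
        break
      }
    }
  }
  list(tree = tree, matrix = m, truth = rbindlist(truth))
}
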