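# Monte-Carlo cross-check of the exact site likelihood.

#' Simulation-based estimate of a site likelihood
#'
#' Estimates the probability of a site pattern by drawing gene trees under
#' the multispecies network coalescent and averaging, per gene tree, the
#' probability of the pattern under the two-state mutation model (computed
#' by exact pruning when one lineage is sampled per species, otherwise by
#' simulating the mutations once per tree).  This estimator shares no code
#' with the exact labeled-partial-likelihood engine and is intended for
#' validating it; the standard error of the estimate is returned alongside.
#'
#' @inheritParams site_likelihood
#' @param n_trees number of gene trees to simulate.
#' @param seed integer seed for the estimator's random stream.
#' @return List with `estimate`, `se` and `n_trees`.
#' @export
site_likelihood_mc <- function(net, pattern, model, n_trees = 1e5,
                               seed = 1L) {
  diag <- validate_network(net, check_times = FALSE)
  if (!diag$ok)
    stop("invalid network: ", paste(diag$violations, collapse = "; "))
  if (any(vapply(pattern, function(p) isTRUE(p$dominant), TRUE)))
    stop("the Monte-Carlo estimator supports co-dominant patterns only")
  nh <- node_heights(net)
  if (!nh$consistent) stop("network branch lengths are time-inconsistent")
  sp <- leaf_labels(net)
  leaf_species <- rep(-1L, n_nodes(net))
  for (i in seq_along(sp))
    leaf_species[which(net$kind == NODE_LEAF & net$label == sp[i])] <- i - 1L
  ord <- rev(topo_order(net))                 # children first, root last
  cpp_site_lik_mc(net$kind, net$eparent, net$echild, net$etheta, net$egamma,
                  nh$heights, net$root, net$root_theta, ord, leaf_species,
                  vapply(pattern[sp], `[[`, 1L, "count"),
                  vapply(pattern[sp], `[[`, 1L, "red"),
                  model$u, model$v, as.integer(n_trees), as.numeric(seed))
}
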