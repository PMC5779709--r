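# Prior on phylogenetic networks and their parameters.
#
# p(net) = p_numret(k | nu) * p_diam(| eta) * p_div(| delta) *
#          p_pop(| zeta) * p_inh(| alpha, beta)
# with a Poisson on the number of reticulations, exponential densities on
# reticulation diameters, an exponential prior on the divergence times
# (root height exponential, other node times uniform given the height, or
# i.i.d. exponentials by option), Gamma(2, zeta) on every branch's
# population mutation rate (mean 2*zeta), and Beta(alpha, beta) on
# inheritance probabilities.  Structurally invalid graphs get prior 0
# (-Inf on the log scale), which is how illegal MCMC proposals are
# rejected.  The Poisson term is normalized by the number of network
# topologies with the same number of reticulations; that count has no
# closed form, so a sequential-attachment surrogate is used: a
# k-reticulation network on n taxa arises from a tree by k successive
# attachments, the j-th choosing an ordered pair of the E_j = 2n - 2 + 3j
# current edges, and on average two attachment representations yield the
# same network, giving N(k) ~ prod_{j<k} E_j (E_j - 1) / 2 (the common
# tree-count factor cancels from all ratios across k).  Without this term
# the prior over k is dominated by the growth in the number of topologies
# and the sampler accumulates likelihood-invisible reticulations; see the
# methods vignette.

#' Prior configuration
#'
#' @param nu Poisson mean for the number of reticulation nodes.
#' @param eta rate of the exponential prior on reticulation diameters.
#' @param delta rate of the exponential prior on divergence times (applied
#'   to the root height under `time_prior = "height-uniform"`).
#' @param zeta scale of the Gamma(2, zeta) prior on per-branch population
#'   mutation rates (mean 2*zeta); `zeta = ptheta/2` for a prior mean
#'   `ptheta`.
#' @param alpha,beta Beta prior on inheritance probabilities;
#'   `alpha = beta = 1` is the uniform prior on [0, 1].
#' @param max_reticulations hard cap on the number of reticulations.
#' @param time_prior `"height-uniform"` (exponential root height, node
#'   times uniform given the height) or `"iid-exponential"`.
#' @return A list of class `"prior_config"`.
#' @export
prior_config <- function(nu = 1, eta = 2, delta = 2, zeta = 0.003,
                         alpha = 1, beta = 1, max_reticulations = 2L,
                         time_prior = c("height-uniform", "iid-exponential")) {
  stopifnot(nu > 0, eta > 0, delta > 0, zeta > 0, alpha > 0, beta > 0,
            max_reticulations >= 0L)
  structure(list(nu = nu, eta = eta, delta = delta, zeta = zeta,
                 alpha = alpha, beta = beta,
                 max_reticulations = as.integer(max_reticulations),
                 time_prior = match.arg(time_prior)),
            class = "prior_config")
}

#' Log prior density of a network
#'
#' Returns `-Inf` for any structurally invalid graph (cycle, bad degrees,
#' gamma pair not summing to one, inconsistent divergence times) or for
#' more than `max_reticulations` reticulations; never throws on such
#' input.
#'
#' @param net a `"phylo_network"` candidate (possibly invalid).
#' @param cfg a [prior_config()].
#' @return Log density (unnormalized across reticulation counts).
#' @export
log_prior <- function(net, cfg) {
  diag <- validate_network(net)
  if (!diag$ok) return(-Inf)
  if (anyDuplicated(paste(net$eparent, net$echild))) return(-Inf)  # parallel edges
  k <- n_reticulations(net)
  if (k > cfg$max_reticulations) return(-Inf)
  nh <- node_heights(net)
  h <- nh$heights[net$root]
  if (!is.finite(h) || h <= 0) return(-Inf)
  internal <- which(net$kind != NODE_LEAF & seq_len(n_nodes(net)) != net$root)
  lp <- stats::dpois(k, cfg$nu, log = TRUE) - log_n_networks(length(leaves(net)), k)
  if (cfg$time_prior == "height-uniform") {
    lp <- lp + stats::dexp(h, cfg$delta, log = TRUE) - length(internal) * log(h)
  } else {
    lp <- lp + stats::dexp(h, cfg$delta, log = TRUE) +
      sum(stats::dexp(nh$heights[internal], cfg$delta, log = TRUE))
  }
  for (v in which(net$kind == NODE_RETIC)) {
    lp <- lp + stats::dexp(reticulation_diameter(net, v), cfg$eta, log = TRUE)
    e1 <- in_edge_idx(net, v)[1L]
    lp <- lp + stats::dbeta(net$egamma[e1], cfg$alpha, cfg$beta, log = TRUE)
  }
  lp <- lp + sum(stats::dgamma(net$etheta, shape = 2, scale = cfg$zeta, log = TRUE))
  if (!is.na(net$root_theta))
    lp <- lp + stats::dgamma(net$root_theta, shape = 2, scale = cfg$zeta, log = TRUE)
  lp
}

# log of the topology-count surrogate N(k) described above
log_n_networks <- function(n_taxa, k) {
  if (k == 0L) return(0)
  Ej <- 2 * n_taxa - 2 + 3 * (seq_len(k) - 1)
  sum(log(Ej) + log(Ej - 1) - log(2))
}

#' Log posterior of a network given markers
#'
#' `dataset_loglik + log_prior`; a `-Inf` prior short-circuits the
#' likelihood evaluation.
#'
#' @inheritParams dataset_loglik
#' @param cfg a [prior_config()].
#' @return Log posterior up to a constant.
#' @export
log_posterior <- function(net, markers, model, cfg, ...) {
  lp <- log_prior(net, cfg)
  if (!is.finite(lp)) return(-Inf)
  lp + dataset_loglik(net, markers, model, ...)
}
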