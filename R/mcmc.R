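# Reversible-jump MCMC over phylogenetic networks, with optional
# Metropolis-coupled (MC^3) pre-burn-in.

# Cached-likelihood closure: unique site patterns, their weights and the
# per-pattern leaf partial vectors are computed once; each call encodes the
# current network and hands everything to the compiled engine.
make_loglik_fn <- function(markers, model,
                           polymorphic_correction = markers$polymorphic_only) {
  up <- unique_patterns(markers)
  np <- length(up$patterns)
  w <- up$weights
  m_total <- sum(w)
  pats <- up$patterns
  if (polymorphic_correction) {
    lc <- lineage_counts(markers)
    sp <- names(markers$taxon_map)
    pats <- c(pats, list(site_pattern(sp, lc$per_species[sp], lc$per_species[sp]),
                         site_pattern(sp, lc$per_species[sp], rep(0L, length(sp)))))
  }
  M <- pattern_M(pats[[1L]])
  l <- n_states(M)
  species <- sort(names(markers$taxon_map))
  # leaf partial vectors are independent of the network topology
  leafF <- array(0, dim = c(l, length(species), length(pats)))
  for (pi in seq_along(pats)) for (j in seq_along(species)) {
    p <- pats[[pi]][[species[j]]]
    leaf <- if (p$dominant) leaf_partials_dominant(p$count, p$red, 0L, M)
            else leaf_partials(p$count, p$red, 0L, M, p$miss)
    leafF[, j, pi] <- leaf$F
  }
  function(net) {
    leaf_slot <- rep(-1L, n_nodes(net))
    lv <- leaves(net)
    leaf_slot[lv] <- match(net$label[lv], species) - 1L
    ret_coord <- rep(-1L, n_nodes(net))
    ret_coord[net$ret_index] <- seq_along(net$ret_index) - 1L
    low <- rep(0L, n_nodes(net))
    low[lowest_articulation_nodes(net)] <- 1L
    ll <- cpp_site_logliks(net$kind, net$eparent, net$echild, net$elen,
                           net$etheta, net$egamma, net$root, net$root_theta,
                           ret_coord, rev(topo_order(net)), low, leaf_slot,
                           leafF, model$u, model$v, M, coord_kill_list(net))
    total <- sum(w * ll[seq_len(np)])
    if (polymorphic_correction)
      total <- total - m_total * log1p(-exp(ll[np + 1L]) - exp(ll[np + 2L]))
    total
  }
}

#' Random starting tree for the sampler
#'
#' A random coalescent-style labelled tree on the given species with
#' staggered node heights and all thetas at the prior mean.
#'
#' @param species character vector of taxon names.
#' @param cfg a [prior_config()] (thetas start at the prior mean 2*zeta).
#' @param height approximate root height (expected mutations per site).
#' @return A `"phylo_network"` with `times` set.
#' @export
random_start_tree <- function(species, cfg, height = 0.05) {
  nsp <- length(species)
  kind <- rep(NODE_LEAF, nsp)
  label <- species
  times <- rep(0, nsp)
  ep <- integer(0); ec <- integer(0)
  active <- seq_len(nsp)
  step <- height / max(nsp - 1L, 1L)
  t <- 0
  while (length(active) > 1L) {
    pair <- sample(active, 2L)
    t <- t + step * stats::runif(1L, 0.5, 1.5)
    kind <- c(kind, NODE_TREE); label <- c(label, ""); times <- c(times, t)
    id <- length(kind)
    ep <- c(ep, id, id); ec <- c(ec, pair)
    active <- c(setdiff(active, pair), id)
  }
  th <- 2 * cfg$zeta
  net <- phylo_network(kind, label, ep, ec, rep(0, length(ep)),
                       rep(th, length(ep)), root_theta = th)
  net$times <- times
  sync_lengths(net)
}

attach_times <- function(net) {
  if (is.null(net$times)) {
    nh <- node_heights(net)
    if (!nh$consistent) stop("starting network is time-inconsistent")
    net$times <- nh$heights
  }
  net
}

run_chain <- function(state, n_iter, loglik_fn, cfg, tune, weights, moves,
                      temp_beta = 1, sample_every = 0L, record = NULL,
                      counts = NULL) {
  if (is.null(counts))
    counts <- matrix(0L, nrow = length(moves), ncol = 2L,
                     dimnames = list(names(moves), c("proposed", "accepted")))
  best <- state
  mv_names <- names(moves)
  pw <- weights[mv_names] / sum(weights[mv_names])
  for (it in seq_len(n_iter)) {
    mi <- sample.int(length(moves), 1L, prob = pw)
    counts[mi, 1L] <- counts[mi, 1L] + 1L
    prop <- moves[[mi]](state$net, cfg, tune)
    if (!is.null(prop)) {
      lp2 <- log_prior(prop$net, cfg)
      if (is.finite(lp2)) {
        ll2 <- if (is.null(loglik_fn)) 0 else loglik_fn(prop$net)
        la <- temp_beta * (ll2 - state$ll) + (lp2 - state$lp) + prop$log_hr
        if (is.finite(la) && log(stats::runif(1L)) < la) {
          state <- list(net = prop$net, ll = ll2, lp = lp2)
          counts[mi, 2L] <- counts[mi, 2L] + 1L
          if (state$ll > best$ll) best <- state
        }
      }
    }
    if (sample_every > 0L && it %% sample_every == 0L && !is.null(record))
      record(state, it)
  }
  list(state = state, best = best, counts = counts)
}

#' Metropolis-coupled pre-burn-in
#'
#' Runs coupled chains with likelihoods heated by 1/T, attempting adjacent
#' temperature swaps periodically, and returns the network with the highest
#' likelihood visited by any chain (used as the starting point of the main
#' sampling phase).
#'
#' @param markers a [marker_matrix()].
#' @param model a [mutation_model()].
#' @param cfg a [prior_config()]; `max_reticulations` may be capped
#'   separately for this phase via `max_ret`.
#' @param temperatures numeric vector including 1.0.
#' @param iterations per-chain iteration count.
#' @param max_ret reticulation cap during pre-burn-in (defaults to the
#'   prior's cap).
#' @param start optional starting `"phylo_network"`; defaults to a random
#'   tree per chain.
#' @param swap_every iterations between swap attempts.
#' @param tune,move_weights sampler tuning (defaults used when `NULL`).
#' @return The highest-likelihood `"phylo_network"` visited.
#' @export
run_mc3_preburnin <- function(markers, model, cfg, temperatures = c(1, 2, 4),
                              iterations = 1000L, max_ret = NULL,
                              start = NULL, swap_every = 20L,
                              tune = NULL, move_weights = NULL) {
  stopifnot(any(temperatures == 1))
  if (is.null(tune)) tune <- default_tuning()
  if (is.null(move_weights)) move_weights <- default_move_weights()
  cfg2 <- cfg
  if (!is.null(max_ret)) cfg2$max_reticulations <- as.integer(max_ret)
  loglik_fn <- make_loglik_fn(markers, model)
  moves <- default_moves()
  nch <- length(temperatures)
  betas <- 1 / temperatures
  states <- vector("list", nch)
  for (i in seq_len(nch)) {
    net <- attach_times(if (is.null(start)) random_start_tree(names(markers$taxon_map), cfg2)
                        else start)
    states[[i]] <- list(net = net, ll = loglik_fn(net), lp = log_prior(net, cfg2))
  }
  best <- states[[which.max(betas)]]
  done <- 0L
  while (done < iterations) {
    todo <- min(swap_every, iterations - done)
    for (i in seq_len(nch)) {
      res <- run_chain(states[[i]], todo, loglik_fn, cfg2, tune, move_weights,
                       moves, temp_beta = betas[i])
      states[[i]] <- res$state
      if (res$best$ll > best$ll) best <- res$best
    }
    done <- done + todo
    if (nch > 1L) {
      a <- sample.int(nch - 1L, 1L)
      la <- (betas[a] - betas[a + 1L]) * (states[[a + 1L]]$ll - states[[a]]$ll)
      if (log(stats::runif(1L)) < la) {
        tmp <- states[[a]]; states[[a]] <- states[[a + 1L]]; states[[a + 1L]] <- tmp
      }
    }
  }
  best$net
}

#' Bayesian inference of a phylogenetic network from bi-allelic markers
#'
#' The package's fitting function: samples the posterior distribution of
#' phylogenetic networks (topology, divergence times, per-branch population
#' mutation rates, inheritance probabilities) given unlinked bi-allelic
#' markers, by reversible-jump MCMC with the exact network likelihood.
#'
#' @param markers a [marker_matrix()].
#' @param model a [mutation_model()].
#' @param prior a [prior_config()].
#' @param chain_length total iterations of the sampling phase.
#' @param burnin iterations discarded before sampling (< `chain_length`).
#' @param sample_freq one sample is collected every `sample_freq`
#'   iterations.
#' @param start optional starting `"phylo_network"`; when `NULL` and
#'   `preburnin_iters > 0`, an MC^3 pre-burn-in selects the start.
#' @param preburnin_iters,preburnin_temps,preburnin_max_ret Metropolis-
#'   coupled pre-burn-in settings (see [run_mc3_preburnin()]).
#' @param seed integer seed; every source of randomness in the run derives
#'   from it.
#' @param threads accepted for interface compatibility; results are
#'   independent of it (fixed reduction order).
#' @param likelihood `"exact"` or `"none"` (prior-only sampling, used to
#'   validate the reversible-jump kernel).
#' @param keep_networks store the sampled networks themselves (disable for
#'   long validation runs; the scalar summaries are always recorded).
#' @param tune,move_weights optional tuning overrides.
#' @return An object of class `"network_mcmc"`: thinned post-burn-in
#'   samples (`$samples` holds the networks; `$k`, `$loglik`, `$logprior`,
#'   `$height` the per-sample summaries), per-move acceptance counts, and
#'   the run configuration.  See [summary.network_mcmc()].
#' @export
network_mcmc <- function(markers, model = mutation_model(),
                         prior = prior_config(),
                         chain_length = 100000L, burnin = 20000L,
                         sample_freq = 500L, start = NULL,
                         preburnin_iters = 0L, preburnin_temps = c(1, 2, 4),
                         preburnin_max_ret = 1L, seed = NULL, threads = 1L,
                         likelihood = c("exact", "none"),
                         keep_networks = TRUE,
                         tune = NULL, move_weights = NULL) {
  likelihood <- match.arg(likelihood)
  stopifnot(burnin < chain_length, sample_freq >= 1L, threads >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(tune)) tune <- default_tuning()
  if (is.null(move_weights)) move_weights <- default_move_weights()
  loglik_fn <- if (likelihood == "exact") make_loglik_fn(markers, model) else NULL
  species <- if (!is.null(markers)) names(markers$taxon_map) else
    stop("markers are required")
  if (is.null(start) && preburnin_iters > 0L && likelihood == "exact") {
    start <- run_mc3_preburnin(markers, model, prior,
                               temperatures = preburnin_temps,
                               iterations = preburnin_iters,
                               max_ret = preburnin_max_ret,
                               tune = tune, move_weights = move_weights)
  }
  net <- attach_times(if (is.null(start)) random_start_tree(species, prior)
                      else start)
  state <- list(net = net,
                ll = if (is.null(loglik_fn)) 0 else loglik_fn(net),
                lp = log_prior(net, prior))
  if (!is.finite(state$lp)) stop("starting network has zero prior probability")
  moves <- default_moves()
  n_samp <- (chain_length - burnin) %/% sample_freq
  samples <- vector("list", n_samp)
  kvec <- integer(n_samp); llv <- numeric(n_samp); lpv <- numeric(n_samp)
  hts <- numeric(n_samp); rth <- numeric(n_samp); gm1 <- rep(NA_real_, n_samp)
  si <- 0L
  counts <- matrix(0L, nrow = length(moves), ncol = 2L,
                   dimnames = list(names(moves), c("proposed", "accepted")))
  # burn-in
  res <- run_chain(state, burnin, loglik_fn, prior, tune, move_weights, moves,
                   counts = counts)
  state <- res$state; counts <- res$counts
  record <- function(st, it) {
    si <<- si + 1L
    if (keep_networks) samples[[si]] <<- st$net
    kvec[si] <<- n_reticulations(st$net)
    llv[si] <<- st$ll; lpv[si] <<- st$lp
    hts[si] <<- st$net$times[st$net$root]
    rth[si] <<- st$net$root_theta
    if (n_reticulations(st$net) > 0L) {
      v <- st$net$ret_index[1L]
      gm1[si] <<- st$net$egamma[in_edge_idx(st$net, v)[1L]]
    }
  }
  res <- run_chain(state, chain_length - burnin, loglik_fn, prior, tune,
                   move_weights, moves, sample_every = sample_freq,
                   record = record, counts = counts)
  counts <- res$counts
  structure(list(samples = if (keep_networks) samples[seq_len(si)] else list(),
                 k = kvec[seq_len(si)],
                 loglik = llv[seq_len(si)], logprior = lpv[seq_len(si)],
                 logpost = llv[seq_len(si)] + lpv[seq_len(si)],
                 height = hts[seq_len(si)],
                 root_theta = rth[seq_len(si)],
                 gamma1 = gm1[seq_len(si)],
                 acceptance = counts, start = net, seed = seed,
                 config = list(chain_length = chain_length, burnin = burnin,
                               sample_freq = sample_freq, prior = prior,
                               likelihood = likelihood)),
            class = "network_mcmc")
}
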