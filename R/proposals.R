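# Reversible-jump MCMC proposal kernel over networks and parameters.
#
# The sampler keeps node divergence times (heights above the leaves) as
# primary coordinates in `net$times`; branch lengths are kept in sync.
# Moves may produce graphs that violate the network definition; those are
# rejected through a zero prior.  Divergence-time consistency, however, is
# guaranteed by construction: time moves are confined to the feasible
# interval and add-reticulation draws the two new times inside theirs.
#
# Moves (chosen from a fixed menu so that selection probabilities cancel
# from the Hastings ratios):
#   time    uniform window on one internal node's time        (symmetric)
#   scale   multiply all internal times by exp(w(U-1/2))      (Jacobian c^m)
#   theta   log-scale sliding window on one branch's theta
#   gamma   reflected uniform window on one reticulation's gamma (symmetric)
#   nni     rooted nearest-neighbour interchange on tree edges (symmetric)
#   add     add a reticulation between a random ordered pair of edges; new
#           times uniform on their feasible intervals, new thetas and gamma
#           drawn from their priors (dimension-matched, unit Jacobian)
#   delete  remove one incoming edge of a random reticulation and suppress
#           the two degree-2 nodes (exact inverse of add)

sync_lengths <- function(net) {
  net$elen <- net$times[net$eparent] - net$times[net$echild]
  net
}

refresh_net <- function(net) {
  net <- sync_lengths(net)
  net$root <- find_root(net)
  net$ret_index <- discover_reticulations(net)
  net
}

# returns list(net, log_hr) or NULL when the proposal is unavailable /
# infeasible (treated as a rejected proposal; the chain does not move)
move_time <- function(net, cfg, tune) {
  internal <- which(net$kind != NODE_LEAF)
  v <- internal[sample.int(length(internal), 1L)]
  lo <- suppressWarnings(max(net$times[children(net, v)]))
  up <- if (v == net$root) Inf else min(net$times[parents(net, v)])
  t2 <- net$times[v] + stats::runif(1L, -tune$time_window / 2, tune$time_window / 2)
  if (t2 <= lo || t2 >= up) return(NULL)
  net$times[v] <- t2
  list(net = sync_lengths(net), log_hr = 0)
}

move_scale <- function(net, cfg, tune) {
  internal <- which(net$kind != NODE_LEAF)
  c <- exp(tune$scale_factor * (stats::runif(1L) - 0.5))
  net$times[internal] <- net$times[internal] * c
  list(net = sync_lengths(net), log_hr = length(internal) * log(c))
}

move_theta <- function(net, cfg, tune) {
  j <- sample.int(n_edges(net) + 1L, 1L)
  f <- exp(tune$theta_window * (stats::runif(1L) - 0.5))
  if (j > n_edges(net)) net$root_theta <- net$root_theta * f
  else net$etheta[j] <- net$etheta[j] * f
  list(net = net, log_hr = log(f))
}

move_gamma <- function(net, cfg, tune) {
  rets <- which(net$kind == NODE_RETIC)
  if (!length(rets)) return(NULL)
  v <- rets[sample.int(length(rets), 1L)]
  es <- in_edge_idx(net, v)
  g <- net$egamma[es[1L]] + stats::runif(1L, -tune$gamma_window, tune$gamma_window)
  while (g < 0 || g > 1) g <- ifelse(g < 0, -g, 2 - g)
  net$egamma[es[1L]] <- g
  net$egamma[es[2L]] <- 1 - g
  list(net = net, log_hr = 0)
}

nni_eligible <- function(net) {
  outdeg <- tabulate(net$eparent, nbins = n_nodes(net))
  which(net$kind[net$echild] == NODE_TREE & outdeg[net$echild] == 2L &
          outdeg[net$eparent] == 2L)
}

move_nni <- function(net, cfg, tune) {
  el <- nni_eligible(net)
  if (!length(el)) return(NULL)
  e <- el[sample.int(length(el), 1L)]
  a <- net$eparent[e]; b <- net$echild[e]
  es_a <- out_edge_idx(net, a)
  e_s <- es_a[es_a != e][1L]          # edge a -> s (sibling of b)
  s <- net$echild[e_s]
  es_b <- out_edge_idx(net, b)
  e_c <- es_b[sample.int(2L, 1L)]     # edge b -> c
  c <- net$echild[e_c]
  if (net$times[b] <= net$times[s]) return(NULL)  # infeasible swap
  net$eparent[e_s] <- b
  net$eparent[e_c] <- a
  list(net = refresh_net(net), log_hr = 0)
}

move_add_reticulation <- function(net, cfg, tune) {
  if (n_reticulations(net) >= cfg$max_reticulations) return(NULL)
  E <- n_edges(net)
  if (E < 2L) return(NULL)
  ij <- sample.int(E, 2L)
  i <- ij[1L]; j <- ij[2L]
  ti_lo <- net$times[net$echild[i]]; ti_hi <- net$times[net$eparent[i]]
  if (ti_hi <= ti_lo) return(NULL)
  th <- stats::runif(1L, ti_lo, ti_hi)
  tj_lo <- max(th, net$times[net$echild[j]]); tj_hi <- net$times[net$eparent[j]]
  if (tj_hi <= tj_lo) return(NULL)
  tw <- stats::runif(1L, tj_lo, tj_hi)
  th_new <- stats::rgamma(3L, shape = 2, scale = cfg$zeta)
  g <- stats::rbeta(1L, cfg$alpha, cfg$beta)

  hN <- length(net$kind) + 1L   # reticulation node on edge i
  wN <- length(net$kind) + 2L   # tree node on edge j
  net$kind <- c(net$kind, NODE_RETIC, NODE_TREE)
  net$label <- c(net$label, "", "")
  net$times <- c(net$times, th, tw)
  Pi <- net$eparent[i]; Ci <- net$echild[i]
  Pj <- net$eparent[j]; Cj <- net$echild[j]
  # lower halves keep the original theta (and gamma when the child is a
  # reticulation); upper halves and the new edge get fresh prior draws
  net$echild[i] <- hN                           # i becomes Pi -> h (upper)
  upper_i_gamma <- NA_real_
  net$eparent <- c(net$eparent, hN, wN, wN)
  net$echild <- c(net$echild, Ci, Cj, hN)
  net$etheta <- c(net$etheta, net$etheta[i], net$etheta[j], th_new[3L])
  net$egamma <- c(net$egamma, net$egamma[i], net$egamma[j], g)
  net$elen <- c(net$elen, 0, 0, 0)              # synced below
  net$etheta[i] <- th_new[1L]; net$egamma[i] <- 1 - g
  net$echild[j] <- wN                           # j becomes Pj -> w (upper)
  net$etheta[j] <- th_new[2L]; net$egamma[j] <- NA_real_

  log_q_add <- -log(E) - log(E - 1L) - log(ti_hi - ti_lo) - log(tj_hi - tj_lo) +
    sum(stats::dgamma(th_new, shape = 2, scale = cfg$zeta, log = TRUE)) +
    stats::dbeta(g, cfg$alpha, cfg$beta, log = TRUE)
  k2 <- n_reticulations(net)
  log_q_del <- -log(k2) - log(2)
  list(net = refresh_net(net), log_hr = log_q_del - log_q_add)
}

move_delete_reticulation <- function(net, cfg, tune) {
  rets <- which(net$kind == NODE_RETIC)
  if (!length(rets)) return(NULL)
  k <- length(rets)
  hN <- rets[sample.int(k, 1L)]
  es <- in_edge_idx(net, hN)
  e_rm <- es[sample.int(2L, 1L)]
  p <- net$eparent[e_rm]
  if (p == net$root || net$kind[p] == NODE_RETIC) return(NULL)
  e_keep <- es[es != e_rm]
  q <- net$eparent[e_keep]
  e_out <- out_edge_idx(net, hN)
  Ci <- net$echild[e_out]
  # record what the reverse add move would have to draw
  th_removed <- c(net$etheta[e_keep], NA, net$etheta[e_rm])
  g_removed <- net$egamma[e_rm]
  t_h <- net$times[hN]
  # suppress h: q -> Ci keeps the lower segment's theta/gamma
  net$eparent[e_out] <- q
  # p loses its edge to h; suppress p similarly
  es_p <- out_edge_idx(net, p)
  e_pc <- es_p[es_p != e_rm]
  pc <- net$echild[e_pc]
  pp_edge <- in_edge_idx(net, p)
  pp <- net$eparent[pp_edge]
  th_removed[2L] <- net$etheta[pp_edge]
  net$eparent[e_pc] <- pp
  net <- drop_edge_rows(net, c(e_rm, e_keep, pp_edge))
  net$kind[hN] <- NODE_TREE        # node dropped below; demote for safety
  # drop the two suppressed nodes
  keepN <- setdiff(seq_len(length(net$kind)), c(hN, p))
  mapN <- integer(length(net$kind)); mapN[keepN] <- seq_along(keepN)
  net$kind <- net$kind[keepN]; net$label <- net$label[keepN]
  net$times <- net$times[keepN]
  net$eparent <- mapN[net$eparent]; net$echild <- mapN[net$echild]
  net <- refresh_net(net)

  # reverse add geometry on the resulting state
  E2 <- n_edges(net)
  Li <- net$times[mapN[q]] - net$times[mapN[Ci]]
  Lj <- net$times[mapN[pp]] - max(t_h, net$times[mapN[pc]])
  if (Li <= 0 || Lj <= 0) return(NULL)
  log_q_add <- -log(E2) - log(E2 - 1L) - log(Li) - log(Lj) +
    sum(stats::dgamma(th_removed, shape = 2, scale = cfg$zeta, log = TRUE)) +
    stats::dbeta(g_removed, cfg$alpha, cfg$beta, log = TRUE)
  log_q_del <- -log(k) - log(2)
  list(net = net, log_hr = log_q_add - log_q_del)
}

# Rooted subtree prune-and-regraft / edge relocation.  Picks an edge
# (p, c) whose parent p is an ordinary internal node (non-root tree node of
# in-degree 1 and out-degree 2), detaches p from its position (suppressing
# it: the sibling edge merges and keeps its own theta, the parent-side
# theta travels with p), and re-inserts p on a random other edge at a
# uniform feasible time.  Because c rides along this relocates whole
# subtrees, and with c a reticulation it relocates a reticulation-edge
# tail.  Dimension-preserving with unit Jacobian (the detached theta is
# carried, not redrawn); the Hastings ratio accounts for the candidate
# counts and the two attachment-interval lengths.
spr_candidates <- function(net) {
  indeg <- tabulate(net$echild, nbins = n_nodes(net))
  outdeg <- tabulate(net$eparent, nbins = n_nodes(net))
  which(net$kind[net$eparent] == NODE_TREE & net$eparent != net$root &
          indeg[net$eparent] == 1L & outdeg[net$eparent] == 2L)
}

move_spr <- function(net, cfg, tune) {
  cand <- spr_candidates(net)
  if (!length(cand)) return(NULL)
  e <- cand[sample.int(length(cand), 1L)]
  p <- net$eparent[e]; cc <- net$echild[e]
  pp_edge <- in_edge_idx(net, p)
  pp <- net$eparent[pp_edge]
  es_p <- out_edge_idx(net, p)
  e_sib <- es_p[es_p != e]
  sib <- net$echild[e_sib]
  theta_carry <- net$etheta[pp_edge]
  L_rev <- net$times[pp] - max(net$times[cc], net$times[sib])
  n_cand <- length(cand)
  # prune: sibling edge merges past p (keeps its own theta/gamma)
  net$eparent[e_sib] <- pp
  net <- drop_edge_rows(net, pp_edge)
  if (e > pp_edge) e <- e - 1L          # row indices shifted by the drop
  # target edge among all remaining edges except (p, c) itself
  E2 <- n_edges(net)
  targets <- setdiff(seq_len(E2), e)
  j <- targets[sample.int(length(targets), 1L)]
  lo <- max(net$times[cc], net$times[net$echild[j]])
  hi <- net$times[net$eparent[j]]
  if (hi <= lo) return(NULL)
  tnew <- stats::runif(1L, lo, hi)
  net$times[p] <- tnew
  # re-insert p on edge j: upper half takes the carried theta
  Cj <- net$echild[j]
  net$eparent <- c(net$eparent, p)
  net$echild <- c(net$echild, Cj)
  net$etheta <- c(net$etheta, net$etheta[j])
  net$egamma <- c(net$egamma, net$egamma[j])
  net$elen <- c(net$elen, 0)
  net$echild[j] <- p
  net$etheta[j] <- theta_carry
  net$egamma[j] <- NA_real_
  net <- refresh_net(net)
  n_cand2 <- length(spr_candidates(net))
  list(net = net,
       log_hr = (-log(n_cand2) - log(L_rev)) - (-log(n_cand) - log(hi - lo)))
}

default_moves <- function() {
  list(time = move_time, scale = move_scale, theta = move_theta,
       gamma = move_gamma, nni = move_nni, spr = move_spr,
       add = move_add_reticulation, delete = move_delete_reticulation)
}

default_move_weights <- function()
  c(time = 0.24, scale = 0.05, theta = 0.20, gamma = 0.10, nni = 0.08,
    spr = 0.13, add = 0.10, delete = 0.10)

default_tuning <- function()
  list(time_window = 0.01, scale_factor = 0.3, theta_window = 1.0,
       gamma_window = 0.15)
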