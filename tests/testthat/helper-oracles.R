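# Independent oracles.  These share no code with the package's likelihood
# path: their own state indexing, their own rate-matrix construction, no
# labels/splits (trees only), and brute-force graph searches.

# --- SNAPP-style species-tree site likelihood (k = 0 only) ----------------
# Partial likelihoods held as (M+1)x(M+1) matrices Fm[n+1, r+1]; bottom-up
# recursion over the tree with the lineage-count/allele-count CTMC per
# branch and the hypergeometric merge at internal nodes.

oracle_Q <- function(theta, u, v, M) {
  states <- do.call(rbind, lapply(0:M, function(n) cbind(n = n, r = 0:n)))
  ns <- nrow(states)
  idx <- function(n, r) which(states[, 1] == n & states[, 2] == r)
  Q <- matrix(0, ns, ns)
  for (s in seq_len(ns)) {
    n <- states[s, 1]; r <- states[s, 2]
    if (n == 0) next
    if (r >= 1) Q[s, idx(n, r - 1)] <- (n - r + 1) * v
    if (r < n) Q[s, idx(n, r + 1)] <- (r + 1) * u
    if (n > 1 && n - 1 - r >= 0 && n - 1 - r != 0)
      Q[s, idx(n - 1, r)] <- (n - 1 - r) * n / theta
    if (r >= 2) Q[s, idx(n - 1, r - 1)] <- (r - 1) * n / theta
    Q[s, s] <- -n * (n - 1) / theta - (n - r) * v - r * u
  }
  list(Q = Q, states = states, idx = idx)
}

oracle_tree_site_lik <- function(net, pattern, model) {
  stopifnot(n_reticulations(net) == 0L)
  u <- model$u; v <- model$v
  M <- sum(vapply(pattern, `[[`, 1L, "count"))
  qq <- oracle_Q(1, u, v, M)   # template for states/idx
  states <- qq$states
  prop_up <- function(vec, theta, t) {
    Q <- oracle_Q(theta, u, v, M)$Q
    as.numeric(vec %*% as.matrix(Matrix::expm(Q * t)))
  }
  combine <- function(f1, f2) {
    out <- numeric(nrow(states))
    nz1 <- which(f1 != 0); nz2 <- which(f2 != 0)
    for (a in nz1) for (b in nz2) {
      n1 <- states[a, 1]; r1 <- states[a, 2]
      n2 <- states[b, 1]; r2 <- states[b, 2]
      n <- n1 + n2; r <- r1 + r2
      if (n > M) next
      w <- choose(r, r1) * choose(n - r, n1 - r1) / choose(n, n1)
      i <- qq$idx(n, r)
      out[i] <- out[i] + f1[a] * f2[b] * w
    }
    out
  }
  rec <- function(v_node) {
    ch_e <- which(net$eparent == v_node)
    if (!length(ch_e)) {  # leaf
      p <- pattern[[net$label[v_node]]]
      f <- numeric(nrow(states))
      f[qq$idx(p$count, p$red)] <- 1
      return(f)
    }
    fs <- lapply(ch_e, function(e)
      prop_up(rec(net$echild[e]), net$etheta[e], net$elen[e]))
    if (length(fs) == 1L) fs[[1L]] else combine(fs[[1L]], fs[[2L]])
  }
  froot <- rec(net$root)
  # stationary vector of the root population by eigen-decomposition
  Q <- oracle_Q(net$root_theta, u, v, M)$Q
  sub <- Q[-1, -1]
  # right null vector of sub, pinned by a sum-to-one row (least squares)
  ns <- nrow(sub)
  x <- qr.solve(rbind(sub, rep(1, ns)), c(rep(0, ns), 1))
  x <- c(0, x)
  x <- x / (x[qq$idx(1, 0)] + x[qq$idx(1, 1)])
  sum(froot * x)
}

# --- dominant-marker leaf partial by exhaustive enumeration ----------------
# F(2 n_x, r) = Pr[band-present individual count = r_x | r red lineages
# among the 2 n_x paired lineages], all C(2 n_x, r) placements equally
# likely.
oracle_dominant_leaf <- function(n_x, r_x, r) {
  lins <- 2L * n_x
  placements <- combn(lins, r)
  if (r == 0L) placements <- matrix(integer(0), nrow = 0, ncol = 1)
  hits <- 0L
  ncols <- ncol(placements)
  for (c in seq_len(ncols)) {
    red <- logical(lins); red[placements[, c]] <- TRUE
    bands <- vapply(seq_len(n_x), function(i)
      any(red[c(2L * i - 1L, 2L * i)]), TRUE)
    if (sum(bands) == r_x) hits <- hits + 1L
  }
  hits / ncols
}

# --- articulation-node brute force ----------------------------------------
# A node separates all of its descendants from the root side: remove it and
# check that no strict descendant remains connected (undirected, including
# the node above the root) to the root component.
oracle_articulation <- function(net) {
  n <- length(net$kind)
  und <- lapply(seq_len(n + 1L), function(i) integer(0))
  for (e in seq_along(net$eparent)) {
    und[[net$eparent[e]]] <- c(und[[net$eparent[e]]], net$echild[e])
    und[[net$echild[e]]] <- c(und[[net$echild[e]]], net$eparent[e])
  }
  und[[n + 1L]] <- net$root
  und[[net$root]] <- c(und[[net$root]], n + 1L)
  desc <- function(v) {
    out <- integer(0); stack <- net$echild[net$eparent == v]
    while (length(stack)) {
      w <- stack[[1L]]; stack <- stack[-1L]
      if (w %in% out) next
      out <- c(out, w)
      stack <- c(stack, net$echild[net$eparent == w])
    }
    out
  }
  vapply(seq_len(n), function(v) {
    d <- desc(v)
    if (!length(d)) return(TRUE)       # leaves: trivially separating
    seen <- logical(n + 1L); seen[v] <- TRUE; seen[n + 1L] <- TRUE
    stack <- n + 1L
    while (length(stack)) {
      a <- stack[[1L]]; stack <- stack[-1L]
      for (b in und[[a]]) if (!seen[b]) { seen[b] <- TRUE; stack <- c(stack, b) }
    }
    !any(seen[d])
  }, TRUE)
}
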