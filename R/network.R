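# Phylogenetic network data model and structural queries.
#
# A network is a rooted binary DAG whose leaves are bijectively labelled by
# taxa.  Nodes of in-degree 2 are reticulations; every edge carries a length
# tau (expected mutations per site) and a population mutation rate theta
# (= 4*N*mu per site), and reticulation edges additionally carry an
# inheritance probability gamma (the pair into one reticulation sums to 1).
# A branch of length tau spans 2*tau/theta coalescent units.  The infinite
# branch above the root has its own theta (`root_theta`).

NODE_LEAF <- 0L
NODE_TREE <- 1L
NODE_RETIC <- 2L

#' Construct a phylogenetic network
#'
#' Low-level constructor from parallel node and edge vectors.  The object is
#' deliberately permissive: structural problems (cycles, bad degrees,
#' inconsistent times) are not errors here but are reported by
#' [validate_network()], because the MCMC sampler relies on proposing
#' slightly invalid graphs and rejecting them through a zero prior.
#'
#' @param kind integer vector, one entry per node: 0 = leaf, 1 = tree node,
#'   2 = reticulation.
#' @param label character vector of node labels; leaves must be uniquely
#'   labelled, internal labels may be `""`.
#' @param parent,child integer vectors defining directed edges
#'   (parent -> child), indices into the node vectors.
#' @param length branch lengths in expected mutations per site.
#' @param theta per-branch population mutation rates.
#' @param gamma inheritance probabilities; `NA` on tree edges.
#' @param root_theta population mutation rate of the infinite branch above
#'   the root.
#' @return An object of class `"phylo_network"`.
#' @export
phylo_network <- function(kind, label, parent, child, length, theta,
                          gamma = rep(NA_real_, base::length(parent)),
                          root_theta = NA_real_) {
  stopifnot(base::length(kind) == base::length(label))
  ne <- base::length(parent)
  stopifnot(base::length(child) == ne, base::length(length) == ne,
            base::length(theta) == ne, base::length(gamma) == ne)
  net <- structure(list(
    kind = as.integer(kind),
    label = as.character(label),
    eparent = as.integer(parent),
    echild = as.integer(child),
    elen = as.numeric(length),
    etheta = as.numeric(theta),
    egamma = as.numeric(gamma),
    root_theta = as.numeric(root_theta)[1]
  ), class = "phylo_network")
  net$root <- find_root(net)
  net$ret_index <- discover_reticulations(net)
  net
}

n_nodes <- function(net) length(net$kind)
n_edges <- function(net) length(net$eparent)

#' @export
n_reticulations <- function(net) sum(net$kind == NODE_RETIC)

find_root <- function(net) {
  indeg <- tabulate(net$echild, nbins = n_nodes(net))
  r <- which(indeg == 0L)
  if (length(r) == 1L) r else NA_integer_
}

# Reticulation ordering 0..k-1 by post-order discovery from the root; LPL
# label coordinates refer to this ordering, so it is persisted on the object.
discover_reticulations <- function(net) {
  if (is.na(net$root)) return(which(net$kind == NODE_RETIC))
  seen <- logical(n_nodes(net))
  found <- integer(0)
  stack <- net$root
  guard <- 0L
  while (length(stack)) {
    guard <- guard + 1L
    if (guard > 4L * n_nodes(net) + 8L) break  # cyclic candidate; bail out
    v <- stack[[1L]]; stack <- stack[-1L]
    if (seen[v]) next
    seen[v] <- TRUE
    if (net$kind[v] == NODE_RETIC) found <- c(found, v)
    stack <- c(children(net, v), stack)
  }
  c(found, setdiff(which(net$kind == NODE_RETIC), found))
}

#' @export
children <- function(net, v) net$echild[net$eparent == v]

#' @export
parents <- function(net, v) net$eparent[net$echild == v]

in_edge_idx <- function(net, v) which(net$echild == v)
out_edge_idx <- function(net, v) which(net$eparent == v)

#' @export
leaves <- function(net) which(net$kind == NODE_LEAF)

#' @export
leaf_labels <- function(net) net$label[leaves(net)]

# Topological order, parents before children; NULL when the graph has a
# directed cycle (Kahn's algorithm).
topo_order <- function(net) {
  n <- n_nodes(net)
  indeg <- tabulate(net$echild, nbins = n)
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (c in children(net, v)) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(ord) != n) NULL else ord
}

# Node heights above the leaves, computed from branch lengths bottom-up.
# Returns list(heights, consistent): `consistent` is FALSE when two paths to
# the same node disagree by more than `tol`, or when the graph is cyclic.
node_heights <- function(net, tol = 1e-9) {
  ord <- topo_order(net)
  if (is.null(ord)) return(list(heights = rep(NA_real_, n_nodes(net)),
                                consistent = FALSE))
  h <- rep(NA_real_, n_nodes(net))
  consistent <- TRUE
  for (v in rev(ord)) {
    if (net$kind[v] == NODE_LEAF) { h[v] <- 0; next }
    hv <- NA_real_
    for (e in out_edge_idx(net, v)) {
      cand <- h[net$echild[e]] + net$elen[e]
      if (is.na(hv)) hv <- cand
      else if (abs(hv - cand) > tol) consistent <- FALSE
    }
    h[v] <- hv
  }
  list(heights = h, consistent = consistent)
}

#' Validate a phylogenetic network
#'
#' Checks the structural invariants of the network definition: a single
#' root, acyclicity, node degrees (tree/leaf nodes have in-degree 1,
#' reticulations in-degree 2 and out-degree 1, no out-degree above 2),
#' gamma pairs summing to 1, uniqueness of leaf labels, positive thetas,
#' nonnegative branch lengths, and divergence-time consistency (no node
#' older than its parent).  Never throws on a structural violation: the
#' sampler relies on the diagnostics to assign prior 0.
#'
#' @param net a `"phylo_network"` (possibly malformed).
#' @param tol numeric tolerance for gamma sums and time consistency.
#' @param check_times also require consistent divergence times (the
#'   likelihood is well defined from branch lengths alone, but the
#'   coalescent simulator and the MCMC sampler need a consistent time
#'   assignment).
#' @return A list with elements `ok` (logical) and `violations`
#'   (character vector naming each failed check).
#' @export
validate_network <- function(net, tol = 1e-9, check_times = TRUE) {
  v <- character(0)
  n <- n_nodes(net)
  indeg <- tabulate(net$echild, nbins = n)
  outdeg <- tabulate(net$eparent, nbins = n)
  if (sum(indeg == 0L) != 1L) v <- c(v, "root: not exactly one in-degree-0 node")
  if (is.null(topo_order(net))) v <- c(v, "cycle: graph has a directed cycle")
  for (i in seq_len(n)) {
    k <- net$kind[i]
    if (k == NODE_LEAF) {
      if (indeg[i] > 1L) v <- c(v, sprintf("degree: leaf %d has in-degree %d", i, indeg[i]))
      if (outdeg[i] != 0L) v <- c(v, sprintf("degree: leaf %d has out-degree %d", i, outdeg[i]))
    } else if (k == NODE_RETIC) {
      if (indeg[i] != 2L) v <- c(v, sprintf("degree: reticulation %d has in-degree %d", i, indeg[i]))
      if (outdeg[i] != 1L) v <- c(v, sprintf("degree: reticulation %d has out-degree %d", i, outdeg[i]))
    } else {
      if (indeg[i] > 1L) v <- c(v, sprintf("degree: tree node %d has in-degree %d", i, indeg[i]))
      if (outdeg[i] > 2L || outdeg[i] == 0L)
        v <- c(v, sprintf("degree: tree node %d has out-degree %d", i, outdeg[i]))
    }
  }
  labs <- leaf_labels(net)
  if (anyDuplicated(labs)) v <- c(v, "labels: duplicate leaf labels")
  if (any(labs == "")) v <- c(v, "labels: unlabelled leaf")
  for (i in which(net$kind == NODE_RETIC)) {
    es <- in_edge_idx(net, i)
    if (length(es) == 2L) {
      g <- net$egamma[es]
      if (anyNA(g)) v <- c(v, sprintf("gamma: missing on a reticulation edge into node %d", i))
      else if (abs(sum(g) - 1) > tol)
        v <- c(v, sprintf("gamma: pair into node %d sums to %.6g", i, sum(g)))
      if (!anyNA(g) && (any(g < -tol) || any(g > 1 + tol)))
        v <- c(v, sprintf("gamma: value outside [0,1] into node %d", i))
    }
  }
  if (any(net$elen < 0, na.rm = TRUE)) v <- c(v, "length: negative branch length")
  if (any(net$etheta <= 0, na.rm = TRUE)) v <- c(v, "theta: non-positive population mutation rate")
  if (check_times) {
    nh <- node_heights(net)
    if (!nh$consistent) v <- c(v, "time: divergence times inconsistent across paths")
  }
  if (check_times && !is.null(net$times)) {
    for (e in seq_len(n_edges(net))) {
      if (!is.na(net$times[net$eparent[e]]) && !is.na(net$times[net$echild[e]]) &&
          net$times[net$eparent[e]] <= net$times[net$echild[e]] - tol) {
        v <- c(v, "time: node with divergence time <= a descendant's")
        break
      }
    }
  }
  list(ok = length(v) == 0L, violations = v)
}

# Undirected adjacency including the special above-root node s (id n+1),
# which matters for articulation-node detection at the root.
undirected_adj <- function(net, with_s = TRUE) {
  n <- n_nodes(net)
  nn <- if (with_s) n + 1L else n
  adj <- vector("list", nn)
  add <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  for (e in seq_len(n_edges(net))) add(net$eparent[e], net$echild[e])
  if (with_s && !is.na(net$root)) add(n + 1L, net$root)
  adj
}

#' Articulation nodes of the network
#'
#' A node whose removal disconnects, in the underlying undirected graph
#' (which includes the special node above the root), every one of its
#' descendants from the root side: every lineage sampled below such a node
#' must exit through it.  In a tree every node qualifies; in a network a
#' node on a reticulation cycle does not, because the cycle provides a
#' bypass around it.  (A node that merely cuts off part of the graph, like
#' the parent of a pendant leaf inside a reticulation cycle, does not
#' separate all of its descendants and is not counted: label bookkeeping
#' from splits below it may still need to resolve above it.)
#' @export
articulation_nodes <- function(net) {
  adj <- undirected_adj(net, with_s = TRUE)
  n <- n_nodes(net)
  s_node <- n + 1L
  desc <- descendant_sets(net)
  out <- integer(0)
  for (v in seq_len(n)) {
    if (net$kind[v] == NODE_LEAF) { out <- c(out, v); next }
    reach <- reachable_without(adj, s_node, v)
    if (!any(reach[desc[[v]]])) out <- c(out, v)
  }
  out
}

# strict descendants per node
descendant_sets <- function(net) {
  ord <- topo_order(net)
  desc <- replicate(n_nodes(net), integer(0), simplify = FALSE)
  for (v in rev(ord)) {
    ch <- children(net, v)
    desc[[v]] <- unique(c(ch, unlist(desc[ch])))
  }
  desc
}

# logical vector of nodes reachable from `from` when `drop` is removed
reachable_without <- function(adj, from, drop) {
  nn <- length(adj)
  seen <- logical(nn)
  seen[drop] <- TRUE
  seen[from] <- TRUE
  stack <- from
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
  }
  seen[drop] <- FALSE
  seen
}

#' Lowest articulation nodes
#'
#' Articulation nodes having at least one child that is neither an
#' articulation node nor a leaf.  At such nodes all labelled partial
#' likelihoods can be collapsed into one by summation, which is the key
#' optimization of the likelihood traversal.  In a tree the set is empty
#' (every node is an articulation node).
#'
#' @param net a valid `"phylo_network"`.
#' @return Integer node ids.
#' @export
lowest_articulation_nodes <- function(net) {
  arts <- articulation_nodes(net)
  is_art <- seq_len(n_nodes(net)) %in% arts
  out <- integer(0)
  for (v in arts) {
    ch <- children(net, v)
    if (any(!is_art[ch] & net$kind[ch] != NODE_LEAF)) out <- c(out, v)
  }
  out
}

#' Diameter of a reticulation node
#'
#' Sum of the branch lengths on the minimal undirected cycle through the
#' reticulation: its two incoming edges plus the shortest undirected path
#' (by total branch length) between its two parents that avoids the
#' reticulation itself.
#'
#' @param net a valid `"phylo_network"`.
#' @param node id of a reticulation node.
#' @return Total branch length of the cycle.
#' @export
reticulation_diameter <- function(net, node) {
  if (net$kind[node] != NODE_RETIC)
    stop("node ", node, " is not a reticulation node")
  es <- in_edge_idx(net, node)
  p <- net$eparent[es]
  # Dijkstra from p[1] to p[2] in the undirected graph minus `node`
  n <- n_nodes(net)
  dist <- rep(Inf, n)
  dist[p[1L]] <- 0
  done <- logical(n)
  done[node] <- TRUE
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    v <- cand[which.min(dist[cand])]
    done[v] <- TRUE
    if (v == p[2L]) break
    for (e in seq_len(n_edges(net))) {
      w <- if (net$eparent[e] == v) net$echild[e]
           else if (net$echild[e] == v) net$eparent[e]
           else next
      if (!done[w] && dist[v] + net$elen[e] < dist[w])
        dist[w] <- dist[v] + net$elen[e]
    }
  }
  if (!is.finite(dist[p[2L]]))
    stop("no undirected cycle through reticulation node ", node)
  dist[p[2L]] + sum(net$elen[es])
}

# Remove an edge and clean up: suppress in-1/out-1 nodes by merging their
# two incident edges (lengths summed, child-side theta kept), demote
# reticulations left with one parent to tree nodes, and re-root when the
# root is left with a single child.  Used by backbone extraction and the
# gamma -> 1 degenerate reduction (where `suppress = FALSE` keeps the
# degree-2 chain with its per-segment thetas).
drop_network_edge <- function(net, eidx, suppress = TRUE) {
  keep <- setdiff(seq_len(n_edges(net)), eidx)
  net$eparent <- net$eparent[keep]; net$echild <- net$echild[keep]
  net$elen <- net$elen[keep]; net$etheta <- net$etheta[keep]
  net$egamma <- net$egamma[keep]
  # demote reticulations with a single remaining parent
  for (v in which(net$kind == NODE_RETIC))
    if (length(in_edge_idx(net, v)) < 2L) {
      net$kind[v] <- NODE_TREE
      net$egamma[in_edge_idx(net, v)] <- NA_real_
    }
  if (suppress) {
    repeat {
      indeg <- tabulate(net$echild, nbins = n_nodes(net))
      outdeg <- tabulate(net$eparent, nbins = n_nodes(net))
      v <- which(net$kind != NODE_LEAF & indeg == 1L & outdeg == 1L)
      if (!length(v)) break
      v <- v[1L]
      ein <- in_edge_idx(net, v); eout <- out_edge_idx(net, v)
      net$eparent[eout] <- net$eparent[ein]
      net$elen[eout] <- net$elen[eout] + net$elen[ein]
      if (!is.na(net$egamma[ein]) && is.na(net$egamma[eout]))
        net$egamma[eout] <- net$egamma[ein]
      net <- drop_edge_rows(net, ein)
    }
    # re-root while the root is an internal node with a single child
    repeat {
      indeg <- tabulate(net$echild, nbins = n_nodes(net))
      outdeg <- tabulate(net$eparent, nbins = n_nodes(net))
      r <- which(indeg == 0L & outdeg == 1L & net$kind != NODE_LEAF)
      if (!length(r)) break
      net <- drop_edge_rows(net, out_edge_idx(net, r[1L]))
    }
    net <- compact_nodes(net)
  }
  net$root <- find_root(net)
  net$ret_index <- discover_reticulations(net)
  net
}

drop_edge_rows <- function(net, eidx) {
  keep <- setdiff(seq_len(n_edges(net)), eidx)
  net$eparent <- net$eparent[keep]; net$echild <- net$echild[keep]
  net$elen <- net$elen[keep]; net$etheta <- net$etheta[keep]
  net$egamma <- net$egamma[keep]
  net
}

# Drop nodes that no longer touch any edge and renumber.
compact_nodes <- function(net) {
  used <- sort(unique(c(net$eparent, net$echild)))
  if (!length(used)) used <- seq_along(net$kind)[net$kind == NODE_LEAF][1]
  map <- integer(n_nodes(net)); map[used] <- seq_along(used)
  net$kind <- net$kind[used]; net$label <- net$label[used]
  if (!is.null(net$times)) net$times <- net$times[used]
  net$eparent <- map[net$eparent]; net$echild <- map[net$echild]
  net
}

#' Backbone tree of a network
#'
#' Deletes, at each reticulation node, the incoming edge with the smaller
#' inheritance probability, then suppresses the resulting degree-2 nodes
#' (their incident branch lengths are summed).  The result is a tree on the
#' same leaf set.
#'
#' @param net a valid `"phylo_network"`.
#' @param tie behaviour at an exact gamma = 0.5 tie: `"error"` (default) or
#'   `"postorder"` (keep the edge whose parent has the smaller post-order
#'   discovery index).
#' @return A `"phylo_network"` with no reticulations.
#' @export
backbone_tree <- function(net, tie = c("error", "postorder")) {
  tie <- match.arg(tie)
  repeat {
    rets <- which(net$kind == NODE_RETIC)
    if (!length(rets)) break
    v <- rets[1L]
    es <- in_edge_idx(net, v)
    g <- net$egamma[es]
    if (abs(g[1L] - g[2L]) < 1e-12) {
      if (tie == "error")
        stop("gamma tie at 0.5 for reticulation node ", v,
             "; set tie = \"postorder\" for a deterministic tie-break")
      ord <- topo_order(net)
      pos <- match(net$eparent[es], ord)
      drop <- es[which.max(pos)]  # keep edge whose parent is discovered earlier
    } else {
      drop <- es[which.min(g)]
    }
    net <- drop_network_edge(net, drop, suppress = TRUE)
  }
  net
}

#' Leaf-label preserving isomorphism between two networks
#'
#' Topology-only comparison (branch lengths, thetas and gammas are
#' ignored).  `network_isomorphism()` returns the node mapping from `n1` to
#' `n2` or `NULL`; `networks_isomorphic()` returns a logical.
#'
#' @param n1,n2 networks on the same leaf set.
#' @return `networks_isomorphic`: TRUE/FALSE. `network_isomorphism`: an
#'   integer vector `map` with `map[v1] = v2`, or `NULL`.
#' @export
networks_isomorphic <- function(n1, n2) !is.null(network_isomorphism(n1, n2))

#' @rdname networks_isomorphic
#' @export
network_isomorphism <- function(n1, n2) {
  if (!setequal(leaf_labels(n1), leaf_labels(n2)))
    stop("networks have different leaf sets")
  if (n_nodes(n1) != n_nodes(n2) || n_edges(n1) != n_edges(n2)) return(NULL)
  if (n_reticulations(n1) != n_reticulations(n2)) return(NULL)
  # hard cluster invariant: set of reachable leaf labels per node
  clus <- function(net) {
    ord <- topo_order(net)
    if (is.null(ord)) return(NULL)
    cl <- vector("list", n_nodes(net))
    for (v in rev(ord)) {
      if (net$kind[v] == NODE_LEAF) cl[[v]] <- net$label[v]
      else cl[[v]] <- sort(unique(unlist(lapply(children(net, v), function(c) cl[[c]]))))
    }
    lapply(cl, paste, collapse = "|")
  }
  c1 <- clus(n1); c2 <- clus(n2)
  if (is.null(c1) || is.null(c2)) return(NULL)
  map <- rep(NA_integer_, n_nodes(n1))
  used <- logical(n_nodes(n2))
  for (v in leaves(n1)) {
    w <- which(n2$kind == NODE_LEAF & n2$label == n1$label[v])
    map[v] <- w; used[w] <- TRUE
  }
  ord1 <- rev(topo_order(n1))  # children before parents
  internal1 <- ord1[n1$kind[ord1] != NODE_LEAF]
  edge_ok <- function(map) {
    # every assigned edge of n1 must exist in n2 and degrees already match
    for (e in seq_len(n_edges(n1))) {
      a <- map[n1$eparent[e]]; b <- map[n1$echild[e]]
      if (is.na(a) || is.na(b)) next
      if (!any(n2$eparent == a & n2$echild == b)) return(FALSE)
    }
    TRUE
  }
  try_assign <- function(i, map, used) {
    if (i > length(internal1)) return(map)
    v <- internal1[i]
    cand <- which(!used & n2$kind == n1$kind[v] & unlist(c2) == c1[[v]])
    for (w in cand) {
      map2 <- map; map2[v] <- w
      used2 <- used; used2[w] <- TRUE
      # children of v must map onto children of w
      chv <- map2[children(n1, v)]
      if (!anyNA(chv) && !setequal(chv, children(n2, w))) next
      if (!edge_ok(map2)) next
      res <- try_assign(i + 1L, map2, used2)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  res <- try_assign(1L, map, used)
  if (is.null(res)) return(NULL)
  if (!edge_ok(res)) return(NULL)
  res
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of nontrivial bipartitions, computed through
#' the standard ape/phangorn route on the plain-Newick export.
#'
#' @param t1,t2 `"phylo_network"` objects with no reticulations, on the
#'   same leaf set.
#' @return Nonnegative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (n_reticulations(t1) > 0L || n_reticulations(t2) > 0L)
    stop("rf_distance is defined for trees (no reticulations)")
  if (!setequal(leaf_labels(t1), leaf_labels(t2)))
    stop("trees have different leaf sets")
  if (!requireNamespace("ape", quietly = TRUE) ||
      !requireNamespace("phangorn", quietly = TRUE))
    stop("rf_distance needs the ape and phangorn packages")
  p1 <- ape::read.tree(text = as_plain_newick(t1))
  p2 <- ape::read.tree(text = as_plain_newick(t2))
  as.integer(phangorn::RF.dist(p1, p2, rooted = FALSE))
}

#' Plain Newick export (trees only)
#' @param net a `"phylo_network"` without reticulations.
#' @return A Newick string with branch lengths.
#' @export
as_plain_newick <- function(net) {
  if (n_reticulations(net) > 0L)
    stop("plain Newick export requires a tree; use write_rich_newick()")
  rec <- function(v, blen) {
    ch <- children(net, v)
    lab <- if (net$kind[v] == NODE_LEAF) net$label[v] else ""
    body <- if (length(ch)) {
      es <- out_edge_idx(net, v)
      paste0("(", paste(vapply(seq_along(es), function(i)
        rec(net$echild[es[i]], net$elen[es[i]]), ""), collapse = ","), ")")
    } else ""
    paste0(body, lab, if (!is.na(blen)) paste0(":", format_num(blen)) else "")
  }
  paste0(rec(net$root, NA_real_), ";")
}

format_num <- function(x) {
  s <- sprintf("%.12g", x)
  s
}

#' @export
print.phylo_network <- function(x, ...) {
  ok <- validate_network(x)$ok
  cat(sprintf("Phylogenetic network: %d leaves (%s), %d reticulation%s, %d edges%s\n",
              length(leaves(x)), paste(sort(leaf_labels(x)), collapse = ", "),
              n_reticulations(x), if (n_reticulations(x) == 1L) "" else "s",
              n_edges(x), if (ok) "" else "  [INVALID]"))
  if (ok && n_reticulations(x) == 0L) cat(" ", as_plain_newick(x), "\n")
  else cat(" ", write_rich_newick(x), "\n")
  invisible(x)
}
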