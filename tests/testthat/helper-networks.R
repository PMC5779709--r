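# Random valid networks for property tests, built directly from node/edge
# vectors (independent of the sampler's proposal machinery).

rand_ultrametric_tree <- function(n_leaves, height = 0.05,
                                  theta_range = c(0.003, 0.01)) {
  species <- LETTERS[seq_len(n_leaves)]
  kind <- rep(0L, n_leaves)
  label <- species
  times <- rep(0, n_leaves)
  ep <- integer(0); ec <- integer(0)
  active <- seq_len(n_leaves)
  hts <- sort(runif(n_leaves - 1L, height * 0.2, height))
  for (j in seq_len(n_leaves - 1L)) {
    pair <- sample(active, 2L)
    kind <- c(kind, 1L); label <- c(label, ""); times <- c(times, hts[j])
    id <- length(kind)
    ep <- c(ep, id, id); ec <- c(ec, pair)
    active <- c(setdiff(active, pair), id)
  }
  th <- runif(length(ep), theta_range[1], theta_range[2])
  net <- phylo_network(kind, label, ep, ec,
                       times[ep] - times[ec], th,
                       root_theta = runif(1, theta_range[1], theta_range[2]))
  net$times <- times
  net
}

# subdivide edges i (head) and j (tail) with a new reticulation
add_random_reticulation <- function(net, theta_range = c(0.003, 0.01)) {
  for (try in 1:50) {
    E <- length(net$eparent)
    ij <- sample.int(E, 2L)
    i <- ij[1]; j <- ij[2]
    lo_i <- net$times[net$echild[i]]; hi_i <- net$times[net$eparent[i]]
    if (hi_i <= lo_i) next
    th_t <- runif(1, lo_i, hi_i)
    lo_j <- max(th_t, net$times[net$echild[j]]); hi_j <- net$times[net$eparent[j]]
    if (hi_j <= lo_j) next
    tw_t <- runif(1, lo_j, hi_j)
    g <- runif(1, 0.1, 0.9)
    hN <- length(net$kind) + 1L; wN <- length(net$kind) + 2L
    net$kind <- c(net$kind, 2L, 1L)
    net$label <- c(net$label, "", "")
    net$times <- c(net$times, th_t, tw_t)
    Ci <- net$echild[i]; Cj <- net$echild[j]
    net$eparent <- c(net$eparent, hN, wN, wN)
    net$echild <- c(net$echild, Ci, Cj, hN)
    net$etheta <- c(net$etheta, net$etheta[i], net$etheta[j],
                    runif(1, theta_range[1], theta_range[2]))
    net$egamma <- c(net$egamma, net$egamma[i], net$egamma[j], g)
    net$elen <- c(net$elen, 0, 0, 0)
    net$echild[i] <- hN
    net$egamma[i] <- 1 - g
    net$etheta[i] <- runif(1, theta_range[1], theta_range[2])
    net$echild[j] <- wN
    net$egamma[j] <- NA_real_
    net$etheta[j] <- runif(1, theta_range[1], theta_range[2])
    net$elen <- net$times[net$eparent] - net$times[net$echild]
    net$root <- markernet:::find_root(net)
    net$ret_index <- markernet:::discover_reticulations(net)
    return(net)
  }
  net
}

rand_network <- function(n_leaves = 4L, n_ret = 1L, height = 0.05,
                         theta_range = c(0.003, 0.01)) {
  net <- rand_ultrametric_tree(n_leaves, height, theta_range)
  for (r in seq_len(n_ret)) net <- add_random_reticulation(net, theta_range)
  net
}

# all site patterns for given per-species lineage counts (co-dominant)
all_patterns <- function(species, counts) {
  grid <- expand.grid(lapply(counts, function(n) 0:n))
  lapply(seq_len(nrow(grid)), function(i)
    site_pattern(species, counts, as.integer(grid[i, ])))
}

# small marker matrix from explicit per-individual values
toy_markers <- function(values, taxon_map, ...) {
  m <- matrix(values, nrow = length(unlist(taxon_map)),
              dimnames = list(unlist(taxon_map), NULL))
  marker_matrix(m, taxon_map, ...)
}
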