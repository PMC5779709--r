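# Simulator of bi-allelic markers on a phylogenetic network: gene trees
# under the multispecies network coalescent, two-state mutation down each
# gene tree, optional polymorphic-site rejection, linked-site blocks, rate
# variation, and diploid / dominant encodings.

#' Simulation configuration
#'
#' @param num_sites total number of sites to generate.
#' @param sites_per_genetree sites sharing one gene tree (linked blocks);
#'   must divide `num_sites`.
#' @param polymorphic_only discard and redraw (gene tree and markers
#'   jointly) until every site in a block is polymorphic.
#' @param diploid,dominant encoding flags (dominant implies diploid; the
#'   red allele is dominant).
#' @param rate_variation `"none"`, `"lineages"` (one rate multiplier per
#'   gene-tree branch) or `"markers"` (one per site).
#' @param inv_prop proportion of invariable draws (multiplier 0).
#' @param gamma_shape shape of the mean-one discrete Gamma for variable
#'   draws.
#' @param n_categories number of equal-probability Gamma categories.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(num_sites, sites_per_genetree = 1L,
                       polymorphic_only = FALSE, diploid = FALSE,
                       dominant = FALSE,
                       rate_variation = c("none", "lineages", "markers"),
                       inv_prop = 0, gamma_shape = 1, n_categories = 1L) {
  rate_variation <- match.arg(rate_variation)
  num_sites <- as.integer(num_sites)
  sites_per_genetree <- as.integer(sites_per_genetree)
  if (num_sites %% sites_per_genetree != 0L)
    stop("num_sites must be divisible by sites_per_genetree")
  if (dominant && !diploid) stop("dominant markers imply diploid individuals")
  stopifnot(inv_prop >= 0, inv_prop < 1, gamma_shape > 0, n_categories >= 1L)
  structure(list(num_sites = num_sites,
                 sites_per_genetree = sites_per_genetree,
                 polymorphic_only = polymorphic_only, diploid = diploid,
                 dominant = dominant, rate_variation = rate_variation,
                 inv_prop = inv_prop, gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories)),
            class = "sim_config")
}

# Equal-probability discrete Gamma category means (mean-one, shape a).
gamma_category_means <- function(a, g) {
  if (g == 1L) return(1)
  qb <- stats::qgamma((0:g) / g, shape = a, rate = a)
  g * (stats::pgamma(qb[-1], shape = a + 1, rate = a) -
         stats::pgamma(qb[-(g + 1)], shape = a + 1, rate = a))
}

draw_rate_multipliers <- function(n, cfg) {
  if (cfg$rate_variation == "none") return(rep(1, n))
  means <- gamma_category_means(cfg$gamma_shape, cfg$n_categories)
  m <- means[sample.int(cfg$n_categories, n, replace = TRUE)]
  m[stats::runif(n) < cfg$inv_prop] <- 0
  m
}

#' Simulate one gene tree under the multispecies network coalescent
#'
#' Lineages start at the leaves (one per sampled lineage), coalesce within
#' each branch as a Kingman coalescent at pairwise rate 2/theta_b per unit
#' of mutation time (a branch of length tau spans 2 tau / theta coalescent
#' units), choose a parent branch independently with probability gamma at
#' each reticulation, and finish coalescing on the infinite branch above
#' the root with the root branch's theta.
#'
#' @param net a valid, time-consistent `"phylo_network"`.
#' @param lineages named integer vector: number of sampled lineages per
#'   species (2 per individual for diploids).
#' @return A gene tree: list with vectors `time`, `c1`, `c2` (children,
#'   `NA` for sampled lineages), `species` (leaf species name or `NA`),
#'   `lineage` (index within species) and scalar `root`.  Uses R's global
#'   RNG stream.
#' @export
sample_gene_tree <- function(net, lineages) {
  nh <- node_heights(net)
  if (!nh$consistent) stop("network branch lengths are time-inconsistent")
  h <- nh$heights
  ntot <- 2L * sum(lineages)      # generous node pool
  time <- numeric(ntot); cc1 <- rep(NA_integer_, ntot); cc2 <- rep(NA_integer_, ntot)
  species <- rep(NA_character_, ntot); lineage <- rep(NA_integer_, ntot)
  nn <- 0L
  surv <- vector("list", n_edges(net))
  coalesce <- function(L, t0, t1, theta) {
    t <- t0
    while (length(L) >= 2L) {
      s <- length(L)
      t <- t + stats::rexp(1L, rate = s * (s - 1) / theta)
      if (t > t1) break
      pair <- sample.int(s, 2L)
      nn <<- nn + 1L
      time[nn] <<- t; cc1[nn] <<- L[pair[1L]]; cc2[nn] <<- L[pair[2L]]
      L <- c(L[-pair], nn)
    }
    L
  }
  groot <- NA_integer_
  for (v in rev(topo_order(net))) {
    if (net$kind[v] == NODE_LEAF) {
      sp <- net$label[v]
      nl <- lineages[[sp]]
      ids <- nn + seq_len(nl)
      time[ids] <- 0; species[ids] <- sp; lineage[ids] <- seq_len(nl)
      nn <- nn + nl
      entering <- ids
    } else {
      entering <- unlist(lapply(out_edge_idx(net, v), function(e) surv[[e]]))
    }
    if (v == net$root) {
      L <- coalesce(entering, h[v], Inf, net$root_theta)
      groot <- L[1L]
    } else if (net$kind[v] == NODE_RETIC) {
      es <- in_edge_idx(net, v)
      take1 <- stats::runif(length(entering)) < net$egamma[es[1L]]
      surv[[es[1L]]] <- coalesce(entering[take1], h[v],
                                 h[net$eparent[es[1L]]], net$etheta[es[1L]])
      surv[[es[2L]]] <- coalesce(entering[!take1], h[v],
                                 h[net$eparent[es[2L]]], net$etheta[es[2L]])
    } else {
      e <- in_edge_idx(net, v)
      surv[[e]] <- coalesce(entering, h[v], h[net$eparent[e]], net$etheta[e])
    }
  }
  keep <- seq_len(nn)
  list(time = time[keep], c1 = cc1[keep], c2 = cc2[keep],
       species = species[keep], lineage = lineage[keep], root = groot)
}

#' Simulate one bi-allelic site down a gene tree
#'
#' The root state is red with probability v/(u+v); mutation then runs
#' forward in time down every branch at rates u (red -> green) and v
#' (green -> red), with branch durations multiplied by `rate_multiplier`
#' (per-site rate variation) and/or `branch_multipliers` (per-lineage rate
#' variation).
#'
#' @param gt a gene tree from [sample_gene_tree()].
#' @param model a [mutation_model()].
#' @param rate_multiplier scalar site rate multiplier.
#' @param branch_multipliers optional vector of per-node (branch above the
#'   node) multipliers.
#' @return Integer vector of colors (1 = red) for the sampled lineages, in
#'   gene-tree node order, with the leaf entries filled.
#' @export
simulate_site <- function(gt, model, rate_multiplier = 1,
                          branch_multipliers = NULL) {
  u <- model$u; v <- model$v; q <- u + v
  piR <- v / q; piG <- u / q
  n <- length(gt$time)
  state <- rep(NA_integer_, n)
  state[gt$root] <- if (stats::runif(1L) < piR) 1L else 0L
  parent <- rep(NA_integer_, n)
  parent[gt$c1[!is.na(gt$c1)]] <- which(!is.na(gt$c1))
  parent[gt$c2[!is.na(gt$c2)]] <- which(!is.na(gt$c2))
  for (i in order(gt$time, decreasing = TRUE)) {
    if (i == gt$root || is.na(parent[i])) next
    t <- (gt$time[parent[i]] - gt$time[i]) * rate_multiplier
    if (!is.null(branch_multipliers)) t <- t * branch_multipliers[i]
    e <- exp(-q * t)
    state[i] <- if (state[parent[i]] == 1L) {
      if (stats::runif(1L) < piG * (1 - e)) 0L else 1L
    } else {
      if (stats::runif(1L) < piR * (1 - e)) 1L else 0L
    }
  }
  ifelse(is.na(gt$c1), state, NA_integer_)[seq_len(n)]
}

#' Encode a diploid individual's two lineages
#'
#' Co-dominant encoding is the red-allele count (0/1/2); dominant encoding
#' is band presence (1 if at least one lineage is red, since heterozygotes
#' and dominant homozygotes are indistinguishable).
#'
#' @param colors integer vector of length 2 (the individual's lineages).
#' @param dominant logical.
#' @return Integer genotype or band indicator.
#' @export
encode_diploid <- function(colors, dominant = FALSE) {
  if (length(colors) != 2L) stop("a diploid individual has exactly 2 lineages")
  if (dominant) as.integer(any(colors == 1L)) else as.integer(sum(colors))
}

#' Simulate a bi-allelic marker matrix on a network
#'
#' Draws one gene tree per block of `sites_per_genetree` sites under the
#' multispecies network coalescent and simulates the two-state mutation
#' process down it for each site of the block.  Under `polymorphic_only`,
#' any block containing a monomorphic site is discarded (gene tree and
#' markers jointly) and redrawn.  Diploid and dominant encodings are
#' applied last; the pairing of the two lineages of an individual is fixed
#' across sites.
#'
#' @param net a valid, time-consistent `"phylo_network"`.
#' @param taxon_map named list: species -> individual ids.
#' @param model a [mutation_model()].
#' @param config a [sim_config()].
#' @return A [marker_matrix()], with attributes `n_gene_trees` (gene trees
#'   actually drawn, including rejected ones) and, when no polymorphic
#'   filter is applied, `polymorphic_fraction`.
#' @export
simulate_bimarkers <- function(net, taxon_map, model, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!setequal(names(taxon_map), leaf_labels(net)))
    stop("taxon map species do not match the network's leaves")
  per_ind <- if (config$diploid) 2L else 1L
  lineages <- vapply(taxon_map, length, 1L) * per_ind
  inds <- unlist(taxon_map, use.names = FALSE)
  nblocks <- config$num_sites %/% config$sites_per_genetree
  out <- matrix(NA_integer_, nrow = length(inds), ncol = config$num_sites,
                dimnames = list(inds, paste0("s", seq_len(config$num_sites))))
  ntrees <- 0L
  npoly <- 0L
  for (b in seq_len(nblocks)) {
    repeat {
      gt <- sample_gene_tree(net, lineages)
      ntrees <- ntrees + 1L
      bm <- if (config$rate_variation == "lineages")
        draw_rate_multipliers(length(gt$time), config) else NULL
      block <- matrix(NA_integer_, length(inds), config$sites_per_genetree)
      poly <- logical(config$sites_per_genetree)
      for (j in seq_len(config$sites_per_genetree)) {
        rm <- if (config$rate_variation == "markers")
          draw_rate_multipliers(1L, config) else 1
        colors <- simulate_site(gt, model, rm, bm)
        leaf_colors <- colors[!is.na(gt$species)]
        leaf_sp <- gt$species[!is.na(gt$species)]
        leaf_li <- gt$lineage[!is.na(gt$species)]
        poly[j] <- any(leaf_colors == 1L) && any(leaf_colors == 0L)
        for (s in names(taxon_map)) {
          cs <- leaf_colors[leaf_sp == s][order(leaf_li[leaf_sp == s])]
          for (ii in seq_along(taxon_map[[s]])) {
            ind <- taxon_map[[s]][ii]
            block[match(ind, inds), j] <- if (config$diploid)
              encode_diploid(cs[(2L * ii - 1L):(2L * ii)], config$dominant)
            else cs[ii]
          }
        }
      }
      if (!config$polymorphic_only || all(poly)) {
        npoly <- npoly + sum(poly)
        cols <- (b - 1L) * config$sites_per_genetree + seq_len(config$sites_per_genetree)
        out[, cols] <- block
        break
      }
    }
  }
  mm <- marker_matrix(out, taxon_map, diploid = config$diploid,
                      dominant = config$dominant,
                      polymorphic_only = config$polymorphic_only)
  attr(mm, "n_gene_trees") <- ntrees
  if (!config$polymorphic_only)
    attr(mm, "polymorphic_fraction") <- npoly / config$num_sites
  mm
}
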