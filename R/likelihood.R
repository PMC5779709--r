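# Network likelihood for one site and for whole marker data sets.
#
# The likelihood of the network given one site integrates over all gene
# trees analytically: a bottom-up traversal initializes partial likelihoods
# at the leaves, propagates them along branches with exp(Qt), splits them in
# every possible way at reticulation nodes (tracking split identity through
# labels), recombines compatible pairs at tree nodes, collapses label
# bookkeeping at lowest articulation nodes, and finally dots the summed
# vector at the root with the single-population stationary distribution.

#' Site pattern constructor
#'
#' A site pattern records, for every species, the sampled lineage/individual
#' count and the observed red total.
#'
#' @param species character vector of species names (must match the
#'   network's leaf labels).
#' @param count per-species lineage counts (individual counts for dominant
#'   markers).
#' @param red per-species observed red totals (band-present individual
#'   counts for dominant markers).
#' @param dominant logical (recycled): dominant-marker encoding per species.
#' @param miss per-species number of lineages with missing state.
#' @return A named list usable as the `pattern` of [site_likelihood()].
#' @export
site_pattern <- function(species, count, red, dominant = FALSE, miss = 0L) {
  count <- rep_len(as.integer(count), length(species))
  red <- rep_len(as.integer(red), length(species))
  dominant <- rep_len(dominant, length(species))
  miss <- rep_len(as.integer(miss), length(species))
  out <- lapply(seq_along(species), function(i)
    list(count = as.integer(count[i]), red = as.integer(red[i]),
         miss = miss[i], dominant = dominant[i]))
  names(out) <- species
  out
}

pattern_M <- function(pattern)
  sum(vapply(pattern, function(p)
    if (p$dominant) 2L * p$count else p$count, 1L))

#' Likelihood of a network for one site
#'
#' Exact probability of the observed site pattern given the network,
#' integrating over all gene trees under the multispecies network
#' coalescent and the two-allele mutation model.
#'
#' @param net a valid `"phylo_network"` with per-branch thetas and a
#'   `root_theta`.
#' @param pattern a [site_pattern()] covering the network's leaf labels.
#' @param model a [mutation_model()].
#' @param engine `"cpp"` (compiled, default) or `"R"` (reference
#'   composition of the exported per-operation functions; same results).
#' @param articulation_opt collapse LPL sets at lowest articulation nodes
#'   (never changes the result; disable only for diagnostics).
#' @return The site likelihood, a probability in [0, 1].
#' @export
site_likelihood <- function(net, pattern, model,
                            engine = c("cpp", "R"),
                            articulation_opt = TRUE) {
  engine <- match.arg(engine)
  diag <- validate_network(net, check_times = FALSE)
  if (!diag$ok)
    stop("invalid network: ", paste(diag$violations, collapse = "; "))
  if (!setequal(names(pattern), leaf_labels(net)))
    stop("pattern species do not match the network's leaves")
  if (engine == "R")
    return(site_likelihood_r(net, pattern, model, articulation_opt))
  exp(engine_logliks(net, list(pattern), model, articulation_opt))
}

# R reference implementation: a literal composition of the per-operation
# surface (leaf_partials, propagate_top, split_at_reticulation,
# merge_at_tree_node, merge_at_articulation, root_stationary).
site_likelihood_r <- function(net, pattern, model, articulation_opt = TRUE) {
  M <- pattern_M(pattern)
  k <- n_reticulations(net)
  low_art <- if (articulation_opt) lowest_articulation_nodes(net) else integer(0)
  Pbot <- vector("list", n_edges(net))
  Ptop <- vector("list", n_edges(net))
  counters <- integer(max(k, 1L))
  Qcache <- list()
  topQ <- function(lpls, eidx) {
    key <- sprintf("%.17g", net$etheta[eidx])
    if (is.null(Qcache[[key]]))
      Qcache[[key]] <<- build_rate_matrix(net$etheta[eidx], model, M)
    propagate_top(lpls, Qcache[[key]], net$elen[eidx])
  }
  finish_edge <- function(eidx, lpls) {
    Pbot[[eidx]] <<- lpls
    Ptop[[eidx]] <<- topQ(lpls, eidx)
  }
  root_set <- NULL
  for (v in rev(topo_order(net))) {
    kind <- net$kind[v]
    if (kind == NODE_LEAF) {
      p <- pattern[[net$label[v]]]
      leaf <- if (p$dominant) leaf_partials_dominant(p$count, p$red, k, M)
              else leaf_partials(p$count, p$red, k, M, p$miss)
      finish_edge(in_edge_idx(net, v), list(leaf))
    } else if (kind == NODE_RETIC) {
      x <- out_edge_idx(net, v)
      S <- Ptop[[x]]
      if (v %in% low_art) S <- merge_at_articulation(S)
      es <- in_edge_idx(net, v)
      coord <- match(v, net$ret_index) - 1L
      sp <- split_at_reticulation(S, net$egamma[es[1L]], coord,
                                  counters[coord + 1L])
      counters[coord + 1L] <- sp$counter
      finish_edge(es[1L], sp$y)
      finish_edge(es[2L], sp$z)
    } else {
      es <- out_edge_idx(net, v)
      B <- if (length(es) == 1L) Ptop[[es]]
           else merge_at_tree_node(Ptop[[es[1L]]], Ptop[[es[2L]]])
      if (v %in% low_art) B <- merge_at_articulation(B)
      if (v == net$root) { root_set <- B; break }
      finish_edge(in_edge_idx(net, v), B)
    }
  }
  Frho <- Reduce(`+`, lapply(root_set, `[[`, "F"))
  x <- root_stationary(net$root_theta, model, M)
  sum(Frho * x)
}

#' Log-likelihood of a network for a marker data set
#'
#' Sum over sites of the log site likelihood.  Unique site patterns are
#' identified first and computed once, with multiplicities as weights; the
#' per-pattern results are combined in a fixed (pattern-sorted) order so
#' the result does not depend on site order or on `threads`.
#'
#' @param net a valid `"phylo_network"`.
#' @param markers a [marker_matrix()].
#' @param model a [mutation_model()].
#' @param threads accepted for interface compatibility; the reduction order
#'   is fixed, so the value never changes the result.
#' @param polymorphic_correction condition each site likelihood on the site
#'   being polymorphic, i.e. divide by 1 - Pr[all red] - Pr[all green].
#'   Defaults to the marker matrix's `polymorphic_only` flag.
#' @param engine `"cpp"` or `"R"` as in [site_likelihood()].
#' @param articulation_opt see [site_likelihood()].
#' @return The log-likelihood (numeric scalar).
#' @export
dataset_loglik <- function(net, markers, model, threads = 1L,
                           polymorphic_correction = markers$polymorphic_only,
                           engine = c("cpp", "R"),
                           articulation_opt = TRUE) {
  engine <- match.arg(engine)
  stopifnot(threads >= 1L)
  if (ncol(markers$data) == 0L) stop("marker matrix has no sites")
  up <- unique_patterns(markers)
  lls <- patterns_loglik(net, up$patterns, model, engine, articulation_opt)
  if (any(!is.finite(lls))) {
    bad <- which(!is.finite(lls))[1L]
    stop("site pattern with zero likelihood: ", up$key[bad])
  }
  total <- sum(up$weights * lls)
  if (polymorphic_correction) {
    lc <- lineage_counts(markers)
    sp <- names(markers$taxon_map)
    mono_red <- site_pattern(sp, lc$per_species[sp], lc$per_species[sp])
    mono_green <- site_pattern(sp, lc$per_species[sp], 0L)
    pm <- exp(patterns_loglik(net, list(mono_red, mono_green), model,
                              engine, articulation_opt))
    total <- total - sum(up$weights) * log1p(-sum(pm))
  }
  total
}

patterns_loglik <- function(net, patterns, model, engine, articulation_opt) {
  diag <- validate_network(net, check_times = FALSE)
  if (!diag$ok)
    stop("invalid network: ", paste(diag$violations, collapse = "; "))
  if (engine == "R")
    vapply(patterns, function(p)
      log(site_likelihood_r(net, p, model, articulation_opt)), 0)
  else
    engine_logliks(net, patterns, model, articulation_opt)
}

# For each edge, the reticulation coordinates that are fully resolved
# there: an edge e "kills" coordinate j when every directed path from
# either parent of reticulation j to the root passes through e, because by
# then both halves of every split at j have been recombined, so the labels
# can be zeroed and LPLs with equal labels summed.  This is the
# per-coordinate generalization of the lowest-articulation-node collapse
# and never changes the likelihood.
coord_kill_list <- function(net) {
  E <- n_edges(net)
  out <- replicate(E, integer(0), simplify = FALSE)
  if (n_reticulations(net) == 0L) return(out)
  reach_root <- function(from, drop_e) {
    stack <- from
    seen <- logical(n_nodes(net))
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (v == net$root) return(TRUE)
      if (seen[v]) next
      seen[v] <- TRUE
      es <- setdiff(which(net$echild == v), drop_e)
      stack <- c(stack, net$eparent[es])
    }
    FALSE
  }
  for (j in seq_along(net$ret_index)) {
    ps <- parents(net, net$ret_index[j])
    for (e in seq_len(E)) {
      if (!reach_root(ps[1L], e) && !reach_root(ps[2L], e))
        out[[e]] <- c(out[[e]], j - 1L)
    }
  }
  out
}

# Bridge into the compiled engine: encode the network and patterns as flat
# arrays once, compute leaf partial vectors with the R surface functions
# (single implementation of the leaf formulas), and hand over.
engine_logliks <- function(net, patterns, model, articulation_opt = TRUE) {
  M <- pattern_M(patterns[[1L]])
  k <- n_reticulations(net)
  l <- n_states(M)
  lv <- leaves(net)
  leaf_slot <- rep(-1L, n_nodes(net))
  leaf_slot[lv] <- seq_along(lv) - 1L
  leafF <- array(0, dim = c(l, length(lv), length(patterns)))
  for (pi in seq_along(patterns)) {
    pat <- patterns[[pi]]
    if (pattern_M(pat) != M) stop("patterns have differing total lineage counts")
    for (j in seq_along(lv)) {
      p <- pat[[net$label[lv[j]]]]
      leaf <- if (p$dominant) leaf_partials_dominant(p$count, p$red, k, M)
              else leaf_partials(p$count, p$red, k, M, p$miss)
      leafF[, j, pi] <- leaf$F
    }
  }
  ret_coord <- rep(-1L, n_nodes(net))
  ret_coord[net$ret_index] <- seq_along(net$ret_index) - 1L
  low <- rep(0L, n_nodes(net))
  if (articulation_opt) low[lowest_articulation_nodes(net)] <- 1L
  cpp_site_logliks(net$kind, net$eparent, net$echild, net$elen, net$etheta,
                   net$egamma, net$root, net$root_theta, ret_coord,
                   rev(topo_order(net)), low, leaf_slot, leafF,
                   model$u, model$v, M, coord_kill_list(net))
}
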