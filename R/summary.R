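# Posterior summaries and S3 methods for network_mcmc fits.

#' @export
print.network_mcmc <- function(x, ...) {
  cat(sprintf("Bayesian phylogenetic network fit: %d posterior samples (chain %d, burn-in %d, thinning %d)\n",
              length(x$samples), x$config$chain_length, x$config$burnin,
              x$config$sample_freq))
  kt <- table(factor(x$k, levels = 0:max(x$k)))
  cat("  reticulation-count posterior: ",
      paste(sprintf("k=%s: %.3f", names(kt), as.numeric(kt) / length(x$k)),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  mean log-likelihood %.3f, mean root height %.5g\n",
              mean(x$loglik), mean(x$height)))
  invisible(x)
}

# Effective sample size from the autocorrelation function (Geyer initial
# positive sequence).
ess <- function(x) {
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  s <- 0; t <- 1L
  while (t + 1L <= length(ac)) {
    pair <- ac[t] + ac[t + 1L]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  n / (1 + 2 * s)
}

# Group sampled networks into topology classes by leaf-labelled isomorphism.
topology_classes <- function(samples) {
  reps <- list(); idx <- integer(length(samples))
  for (i in seq_along(samples)) {
    hit <- 0L
    for (j in seq_along(reps)) {
      if (n_reticulations(reps[[j]]) == n_reticulations(samples[[i]]) &&
          networks_isomorphic(reps[[j]], samples[[i]])) { hit <- j; break }
    }
    if (hit == 0L) { reps[[length(reps) + 1L]] <- samples[[i]]; hit <- length(reps) }
    idx[i] <- hit
  }
  list(representatives = reps, index = idx)
}

#' Summarize a network MCMC fit
#'
#' Computes the posterior distribution of the reticulation count, the
#' maximum a posteriori topology (the topology class with the highest
#' posterior frequency, reported with its best-log-posterior member), an
#' effective sample size for the log posterior, and posterior means of the
#' root height.
#'
#' @param object a `"network_mcmc"` fit.
#' @param ... unused.
#' @return A list of class `"summary.network_mcmc"`.
#' @export
summary.network_mcmc <- function(object, ...) {
  if (!length(object$samples)) stop("empty trace")
  tc <- topology_classes(object$samples)
  freq <- tabulate(tc$index, nbins = length(tc$representatives)) /
    length(object$samples)
  map_class <- which.max(freq)
  in_map <- which(tc$index == map_class)
  map_net <- object$samples[[in_map[which.max(object$logpost[in_map])]]]
  kdist <- table(factor(object$k, levels = 0:max(object$k))) / length(object$k)
  structure(list(n_samples = length(object$samples),
                 k_posterior = kdist,
                 map_network = map_net,
                 map_frequency = freq[map_class],
                 topology_frequencies = sort(freq, decreasing = TRUE),
                 ess_logpost = ess(object$logpost),
                 mean_height = mean(object$height),
                 acceptance = object$acceptance),
            class = "summary.network_mcmc")
}

#' @export
print.summary.network_mcmc <- function(x, ...) {
  cat(sprintf("Posterior summary over %d samples (ESS of log posterior: %.0f)\n",
              x$n_samples, x$ess_logpost))
  cat("  k posterior:", paste(sprintf("k=%s: %.3f", names(x$k_posterior),
                                      as.numeric(x$k_posterior)), collapse = ", "), "\n")
  cat(sprintf("  MAP topology (frequency %.3f):\n    %s\n", x$map_frequency,
              write_rich_newick(x$map_network)))
  cat(sprintf("  posterior mean root height: %.5g\n", x$mean_height))
  acc <- x$acceptance
  cat("  acceptance rates: ",
      paste(sprintf("%s %.2f", rownames(acc),
                    ifelse(acc[, 1] > 0, acc[, 2] / acc[, 1], NA)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
plot.network_mcmc <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$logpost, type = "l", xlab = "sample", ylab = "log posterior",
                 main = "Trace of the log posterior")
  graphics::plot(x$k, type = "s", xlab = "sample", ylab = "reticulations (k)",
                 main = "Trace of the reticulation count")
  invisible(x)
}

#' @export
coef.network_mcmc <- function(object, ...) {
  c(mean_root_height = mean(object$height),
    mean_k = mean(object$k),
    mean_loglik = mean(object$loglik))
}

#' Posterior frequency of a reference topology and its inheritance
#' probability
#'
#' For every sample isomorphic to `reference`, extracts the inheritance
#' probability of the sample edge corresponding to the reference's
#' minor (smaller-gamma) reticulation edge.
#'
#' @param fit a `"network_mcmc"`.
#' @param reference a `"phylo_network"` (with at least one reticulation for
#'   gamma extraction).
#' @return List with `match_frequency` and `gamma` (vector over matching
#'   samples, minor-edge inheritance probabilities; empty when the
#'   reference is a tree).
#' @export
match_reference_topology <- function(fit, reference) {
  hit <- logical(length(fit$samples))
  gammas <- numeric(0)
  ref_minor <- NULL
  if (n_reticulations(reference) > 0L) {
    v <- reference$ret_index[1L]
    es <- in_edge_idx(reference, v)
    ref_minor <- es[which.min(reference$egamma[es])]
  }
  for (i in seq_along(fit$samples)) {
    s <- fit$samples[[i]]
    if (n_reticulations(s) != n_reticulations(reference)) next
    map <- tryCatch(network_isomorphism(reference, s), error = function(e) NULL)
    if (is.null(map)) next
    hit[i] <- TRUE
    if (!is.null(ref_minor)) {
      a <- map[reference$eparent[ref_minor]]
      b <- map[reference$echild[ref_minor]]
      e2 <- which(s$eparent == a & s$echild == b)
      gammas <- c(gammas, s$egamma[e2])
    }
  }
  list(match_frequency = mean(hit), gamma = gammas)
}
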