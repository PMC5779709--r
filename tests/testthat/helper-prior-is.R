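# Importance-sampling estimate of the prior mass of k = 1 networks on
# three taxa with max_reticulations = 1.  Draws come from a fully tractable
# generative distribution q (uniform topology/attachment, exponential root
# height, uniform node times, prior-distributed thetas and gammas); each
# draw is weighted by p/q with p = exp(log_prior).  Because the theta,
# gamma and time factors of q match the prior exactly, the weights reduce
# to the Poisson and diameter terms, but the code evaluates p/q in full.
# This estimates the same (unnormalized) prior the sampler targets, without
# using any proposal machinery, so it validates the reversible-jump
# Hastings ratios.

prior_is_k1 <- function(cfg, n_draws = 20000L) {
  species <- c("A", "B", "C")
  trees <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 3L, 1L))  # (ab)c
  logw <- numeric(n_draws)
  isk1 <- logical(n_draws)
  for (d in seq_len(n_draws)) {
    k <- sample(0:1, 1L)
    ti <- sample.int(3L, 1L)
    ab <- trees[[ti]][1:2]; cc <- trees[[ti]][3]
    h <- rexp(1, cfg$delta)
    t_x <- runif(1, 0, h)
    # nodes: 1..3 leaves, 4 = x, 5 = root
    kind <- c(0L, 0L, 0L, 1L, 1L)
    times <- c(0, 0, 0, t_x, h)
    ep <- c(5L, 4L, 4L, 5L)
    ec <- c(4L, ab, cc)
    n_unif <- 1L
    lq_top <- log(1 / 2) + log(1 / 3)
    if (k == 1L) {
      ij <- sample.int(4L, 2L)
      t_h <- runif(1, 0, h); t_w <- runif(1, 0, h)
      n_unif <- 3L
      lq_top <- lq_top + log(1 / 12)
      hN <- 6L; wN <- 7L
      kind <- c(kind, 2L, 1L)
      times <- c(times, t_h, t_w)
      Ci <- ec[ij[1]]; Cj <- ec[ij[2]]
      ep <- c(ep, hN, wN, wN)
      ec <- c(ec, Ci, Cj, hN)
      ec[ij[1]] <- hN
      ec[ij[2]] <- wN
    }
    ne <- length(ep)
    th <- rgamma(ne + 1L, shape = 2, scale = cfg$zeta)
    gam <- rep(NA_real_, ne)
    lq_par <- sum(dgamma(th, shape = 2, scale = cfg$zeta, log = TRUE))
    if (k == 1L) {
      g <- rbeta(1, cfg$alpha, cfg$beta)
      e_new <- ne                      # edge w -> h is last
      e_up <- ij[1]                    # upper half of edge i, into h
      gam[e_new] <- g
      gam[e_up] <- 1 - g
      lq_par <- lq_par + dbeta(g, cfg$alpha, cfg$beta, log = TRUE)
    }
    net <- phylo_network(kind, c(species, rep("", length(kind) - 3L)),
                         ep, ec, times[ep] - times[ec], th[seq_len(ne)],
                         gam, root_theta = th[ne + 1L])
    net$times <- times
    lp <- log_prior(net, cfg)
    if (!is.finite(lp)) { logw[d] <- -Inf; isk1[d] <- (k == 1L); next }
    lq <- lq_top + dexp(h, cfg$delta, log = TRUE) - n_unif * log(h) + lq_par
    # chart multiplicity: the same abstract network is generated by a second
    # (tree, head-edge, tail-edge) chart whenever the head's other parent is
    # an ordinary internal node rather than the root, so the total proposal
    # density at the network is m * q
    if (k == 1L) {
      m <- 1L + as.integer(ep[ij[1]] != 5L)
      lq <- lq + log(m)
    }
    logw[d] <- lp - lq
    isk1[d] <- (k == 1L)
  }
  w <- exp(logw - max(logw[is.finite(logw)]))
  R <- sum(w[isk1]) / sum(w)
  # influence-function standard error of the ratio estimator
  infl <- (as.numeric(isk1) - R) * w / mean(w)
  list(p_k1 = R, se = stats::sd(infl) / sqrt(n_draws))
}
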