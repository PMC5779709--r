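small_markers <- function(net, n_sites = 40L, seed = 5) {
  sp <- leaf_labels(net)
  tm <- as.list(paste0(tolower(sp), "1")); names(tm) <- sp
  set.seed(seed)
  simulate_bimarkers(net, tm, mutation_model(), sim_config(n_sites))
}

test_that("the trace holds (chain length - burn-in) / frequency samples", {
  net <- rand_ultrametric_tree(3)
  mm <- small_markers(net, 20)
  fit <- network_mcmc(mm, prior = prior_config(max_reticulations = 1L),
                      chain_length = 10000L, burnin = 2000L,
                      sample_freq = 500L, seed = 9,
                      likelihood = "none")
  expect_length(fit$k, 16L)
})

test_that("fixed seeds reproduce the trace exactly", {
  net <- rand_ultrametric_tree(3)
  mm <- small_markers(net, 20)
  run <- function() network_mcmc(mm, prior = prior_config(max_reticulations = 1L),
                                 chain_length = 4000L, burnin = 500L,
                                 sample_freq = 100L, seed = 123)
  f1 <- run(); f2 <- run()
  expect_identical(f1$logpost, f2$logpost)
  expect_identical(f1$k, f2$k)
})

test_that("every sampled network is valid with consistent divergence times", {
  net <- rand_ultrametric_tree(3)
  mm <- small_markers(net, 20)
  fit <- network_mcmc(mm, prior = prior_config(max_reticulations = 2L),
                      chain_length = 6000L, burnin = 1000L,
                      sample_freq = 100L, seed = 31)
  for (s in fit$samples) {
    d <- validate_network(s)
    expect_true(d$ok)
    expect_true(all(s$times[s$eparent] > s$times[s$echild]))
  }
})

test_that("cached log posteriors match independent recomputation", {
  net <- rand_ultrametric_tree(3)
  mm <- small_markers(net, 30)
  cfg <- prior_config(max_reticulations = 1L)
  mod <- mutation_model()
  fit <- network_mcmc(mm, model = mod, prior = cfg,
                      chain_length = 4000L, burnin = 500L,
                      sample_freq = 250L, seed = 77)
  idx <- sample(seq_along(fit$samples), min(10, length(fit$samples)))
  for (i in idx) {
    s <- fit$samples[[i]]
    expect_equal(fit$loglik[i], dataset_loglik(s, mm, mod), tolerance = 1e-9)
    expect_equal(fit$logprior[i], log_prior(s, cfg), tolerance = 1e-9)
  }
})

test_that("MC3 pre-burn-in returns a network at least as good as a cold start", {
  net <- example_network("net5_1ret")
  mm <- small_markers(net, 60, seed = 8)
  mod <- mutation_model()
  cfg <- prior_config(max_reticulations = 1L)
  set.seed(42)
  start <- random_start_tree(names(mm$taxon_map), cfg)
  best <- run_mc3_preburnin(mm, mod, cfg, temperatures = c(1, 2, 4),
                            iterations = 300L, start = start)
  expect_gte(dataset_loglik(best, mm, mod), dataset_loglik(start, mm, mod))
  expect_true(validate_network(best)$ok)
})

test_that("data simulated on a tree keep the sampler on that tree", {
  tr <- read_rich_newick(paste0(
    "[0.006](((A:0.01:0.006,B:0.01:0.006):0.01:0.005,C:0.02:0.006)",
    ":0.02:0.005,(D:0.025:0.006,E:0.025:0.006):0.015:0.005);"))
  sp <- leaf_labels(tr)
  tm <- as.list(paste0(tolower(sp), "1")); names(tm) <- sp
  set.seed(14)
  mm <- simulate_bimarkers(tr, tm, mutation_model(), sim_config(10000))
  fit <- network_mcmc(mm, prior = prior_config(nu = 1, max_reticulations = 2L),
                      chain_length = 30000L, burnin = 5000L,
                      sample_freq = 50L, seed = 15)
  # the overwhelming majority of samples are trees, and the sampled trees
  # are the true topology
  expect_gte(mean(fit$k == 0), 0.85)
  m <- match_reference_topology(fit, tr)
  expect_gte(m$match_frequency, 0.85)
})

test_that("prior-only sampling reproduces the prior's k mass and parameter marginals", {
  cfg <- prior_config(nu = 0.8, eta = 4, delta = 30, zeta = 0.004,
                      alpha = 2, beta = 2, max_reticulations = 1L)
  set.seed(61)
  is_est <- prior_is_k1(cfg, n_draws = 15000L)
  start <- random_start_tree(c("A", "B", "C"), cfg, height = 1 / 30)
  fit <- network_mcmc(markers = toy_markers(matrix(c(0L, 1L, 0L), nrow = 3),
                                            list(A = "a", B = "b", C = "c")),
                      prior = cfg, chain_length = 1.2e5, burnin = 1e4,
                      sample_freq = 10L, start = start, seed = 62,
                      likelihood = "none", keep_networks = FALSE)
  p_chain <- mean(fit$k == 1)
  ess_k <- markernet:::ess(as.numeric(fit$k == 1))
  se_chain <- sqrt(p_chain * (1 - p_chain) / ess_k)
  z <- abs(p_chain - is_est$p_k1) / sqrt(se_chain^2 + is_est$se^2)
  expect_lt(z, 4)
  # the exact Gamma/Beta marginal checks run at full scale in the
  # acceptance suite; here just require the sampled parameters to move
  expect_gt(length(unique(fit$root_theta)), 1000)
  expect_gt(sum(!is.na(fit$gamma1)), 100)
})

test_that("summaries identify the MAP topology and a sane ESS", {
  net <- rand_ultrametric_tree(3)
  mm <- small_markers(net, 30)
  fit <- network_mcmc(mm, prior = prior_config(max_reticulations = 1L),
                      chain_length = 5000L, burnin = 1000L,
                      sample_freq = 100L, seed = 21)
  s <- summary(fit)
  expect_equal(sum(as.numeric(s$k_posterior)), 1, tolerance = 1e-12)
  expect_true(validate_network(s$map_network)$ok)
  expect_gte(s$map_frequency, max(s$topology_frequencies))
  # ESS of white noise is close to the sample count
  set.seed(3)
  x <- rnorm(2000)
  expect_lt(abs(markernet:::ess(x) - 2000) / 2000, 0.2)
  # trace of identical samples: MAP frequency 1
  fit2 <- fit
  fit2$samples <- rep(fit$samples[1], 10)
  fit2$k <- rep(fit$k[1], 10); fit2$logpost <- rep(fit$logpost[1], 10)
  fit2$loglik <- fit2$logpost; fit2$logprior <- rep(0, 10)
  fit2$height <- rep(fit$height[1], 10)
  s2 <- summary(fit2)
  expect_equal(s2$map_frequency, 1)
})

test_that("reference-topology matching extracts the minor-edge gamma", {
  net <- example_network("net5_1ret")
  fit <- list(samples = list(net, backbone_tree(net), net),
              logpost = c(-1, -2, -0.5))
  class(fit) <- "network_mcmc"
  m <- match_reference_topology(fit, net)
  expect_equal(m$match_frequency, 2 / 3)
  expect_equal(m$gamma, c(0.3, 0.3))
})
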