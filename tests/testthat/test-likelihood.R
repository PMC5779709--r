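mod11 <- mutation_model(1, 1)

test_that("a single red lineage has likelihood v/(u+v) for any branch lengths", {
  for (t in c(0.001, 0.37, 5)) {
    net <- read_rich_newick(sprintf("[0.006](A:%g:0.004);", t))
    expect_equal(site_likelihood(net, site_pattern("A", 1, 1), mod11), 0.5,
                 tolerance = 1e-12)
    mod <- mutation_model(u = 2, v = 0.5)
    expect_equal(site_likelihood(net, site_pattern("A", 1, 1), mod), 0.5 / 2.5,
                 tolerance = 1e-12)
    expect_equal(site_likelihood(net, site_pattern("A", 1, 0), mod), 2 / 2.5,
                 tolerance = 1e-12)
  }
})

test_that("site likelihoods sum to one over all patterns on random networks", {
  set.seed(31)
  for (i in 1:12) {
    nl <- sample(2:4, 1)
    net <- rand_network(nl, sample(0:2, 1))
    counts <- sample(1:2, nl, replace = TRUE)
    pats <- all_patterns(leaf_labels(net), counts)
    tot_c <- sum(vapply(pats, function(p) site_likelihood(net, p, mod11), 0))
    tot_n <- sum(vapply(pats, function(p)
      site_likelihood(net, p, mod11, articulation_opt = FALSE), 0))
    expect_equal(tot_c, 1, tolerance = 1e-8)
    expect_equal(tot_n, 1, tolerance = 1e-8)
  }
})

test_that("the R reference and compiled engines agree to 1e-12", {
  set.seed(32)
  for (i in 1:8) {
    nl <- sample(2:4, 1)
    net <- rand_network(nl, sample(0:2, 1))
    counts <- sample(1:2, nl, replace = TRUE)
    for (p in sample(all_patterns(leaf_labels(net), counts), 4)) {
      a <- site_likelihood(net, p, mod11, engine = "cpp")
      b <- site_likelihood(net, p, mod11, engine = "R")
      expect_equal(a, b, tolerance = 1e-12)
    }
  }
})

test_that("on trees the network engine equals the SNAPP-style tree oracle", {
  set.seed(33)
  mods <- list(mod11, mutation_model(u = 1.6, v = 0.7))
  for (i in 1:10) {
    nl <- sample(2:4, 1)
    net <- rand_ultrametric_tree(nl)
    counts <- sample(1:2, nl, replace = TRUE)
    mod <- mods[[1 + i %% 2]]
    for (p in sample(all_patterns(leaf_labels(net), counts), 3)) {
      expect_lt(abs(site_likelihood(net, p, mod) -
                      oracle_tree_site_lik(net, p, mod)), 1e-12)
    }
  }
})

test_that("setting gamma to 1 reduces to the network with the minor edge deleted", {
  set.seed(34)
  for (i in 1:6) {
    net <- rand_network(sample(2:4, 1), 1)
    v <- net$ret_index[1]
    es <- which(net$echild == v)
    net$egamma[es[1]] <- 1; net$egamma[es[2]] <- 0
    reduced <- markernet:::drop_network_edge(net, es[2], suppress = FALSE)
    counts <- rep(1L, length(leaves(net)))
    for (p in sample(all_patterns(leaf_labels(net), counts), 3)) {
      expect_equal(site_likelihood(net, p, mod11),
                   site_likelihood(reduced, p, mod11), tolerance = 1e-10)
    }
  }
})

test_that("a single-lineage reticulation gives the gamma mixture of forced routings", {
  net <- example_network("net5_1ret")   # only Q's lineage reaches the reticulation
  v <- net$ret_index[1]
  es <- which(net$echild == v)
  g <- net$egamma[es[1]]
  left <- net;  left$egamma[es]  <- c(1, 0)
  right <- net; right$egamma[es] <- c(0, 1)
  sp <- leaf_labels(net)
  set.seed(35)
  for (i in 1:5) {
    p <- site_pattern(sp, rep(1, 5), sample(0:1, 5, replace = TRUE))
    expect_equal(site_likelihood(net, p, mod11),
                 g * site_likelihood(left, p, mod11) +
                   (1 - g) * site_likelihood(right, p, mod11),
                 tolerance = 1e-10)
  }
})

test_that("exact site likelihoods agree with the gene-tree Monte-Carlo estimator", {
  set.seed(36)
  cases <- 0
  while (cases < 6) {
    net <- rand_network(sample(3:4, 1), sample(0:1, 1))
    sp <- leaf_labels(net)
    p <- site_pattern(sp, rep(1, length(sp)), sample(0:1, length(sp), replace = TRUE))
    ex <- site_likelihood(net, p, mod11)
    if (ex < 0.005) next
    mc <- site_likelihood_mc(net, p, mod11, n_trees = 4e4, seed = 100 + cases)
    expect_lt(abs(ex - mc$estimate), 3 * mc$se + 1e-12)
    cases <- cases + 1
  }
})

test_that("dataset log-likelihood handles weights, duplication and threads deterministically", {
  tm <- list(A = "a1", B = "b1", C = "c1")
  net <- rand_ultrametric_tree(3)
  set.seed(37)
  vals <- matrix(sample(0:1, 3 * 6, replace = TRUE), nrow = 3)
  vals[, 6] <- vals[, 5]                       # duplicated column
  mm <- toy_markers(vals, tm)
  ll <- dataset_loglik(net, mm, mod11)
  persite <- sum(vapply(seq_len(6), function(i)
    log(site_likelihood(net, site_pattern(names(tm), rep(1, 3), vals[, i]), mod11)), 0))
  expect_equal(ll, persite, tolerance = 1e-12)
  expect_identical(dataset_loglik(net, mm, mod11, threads = 1),
                   dataset_loglik(net, mm, mod11, threads = 8))
  # m identical columns give m * log(site likelihood)
  mm1 <- toy_markers(matrix(rep(c(1L, 0L, 1L), 4), nrow = 3), tm)
  l1 <- log(site_likelihood(net, site_pattern(names(tm), rep(1, 3), c(1, 0, 1)), mod11))
  expect_equal(dataset_loglik(net, mm1, mod11), 4 * l1, tolerance = 1e-12)
})

test_that("polymorphic-only conditioning divides by the polymorphism probability", {
  tm <- list(A = "a1", B = "b1")
  net <- rand_ultrametric_tree(2)
  mm <- toy_markers(matrix(c(1L, 0L, 0L, 1L), nrow = 2), tm, polymorphic_only = TRUE)
  sp <- names(tm)
  pmono <- site_likelihood(net, site_pattern(sp, c(1, 1), c(1, 1)), mod11) +
    site_likelihood(net, site_pattern(sp, c(1, 1), c(0, 0)), mod11)
  raw <- sum(log(c(
    site_likelihood(net, site_pattern(sp, c(1, 1), c(1, 0)), mod11),
    site_likelihood(net, site_pattern(sp, c(1, 1), c(0, 1)), mod11))))
  expect_equal(dataset_loglik(net, mm, mod11), raw - 2 * log1p(-pmono),
               tolerance = 1e-12)
  # without the flag the correction is off
  mm2 <- toy_markers(matrix(c(1L, 0L, 0L, 1L), nrow = 2), tm)
  expect_equal(dataset_loglik(net, mm2, mod11), raw, tolerance = 1e-12)
  # conditioned site likelihoods renormalize over polymorphic patterns
  cond <- (1 - pmono)
  tot <- (exp(raw / 1)) # unused guard
  expect_gt(dataset_loglik(net, mm, mod11), raw)
})

test_that("diploid and dominant data sets are encoded into valid likelihoods", {
  tm <- list(A = "a1", B = "b1")
  net <- rand_ultrametric_tree(2)
  mmd <- toy_markers(matrix(c(2L, 1L, 0L, 1L), nrow = 2), tm, diploid = TRUE)
  lld <- dataset_loglik(net, mmd, mod11)
  expect_true(is.finite(lld) && lld < 0)
  sp <- names(tm)
  expect_equal(lld,
               log(site_likelihood(net, site_pattern(sp, c(2, 2), c(2, 1)), mod11)) +
               log(site_likelihood(net, site_pattern(sp, c(2, 2), c(0, 1)), mod11)),
               tolerance = 1e-12)
  mmb <- toy_markers(matrix(c(1L, 0L, 1L, 1L), nrow = 2), tm,
                     diploid = TRUE, dominant = TRUE)
  llb <- dataset_loglik(net, mmb, mod11)
  expect_equal(llb,
               log(site_likelihood(net, site_pattern(sp, c(1, 1), c(1, 0), dominant = TRUE), mod11)) +
               log(site_likelihood(net, site_pattern(sp, c(1, 1), c(1, 1), dominant = TRUE), mod11)),
               tolerance = 1e-12)
})

test_that("missing marker entries are integrated out of the leaf partials", {
  tm <- list(A = c("a1", "a2"), B = "b1")
  net <- rand_ultrametric_tree(2)
  vals <- matrix(c(1L, NA, 0L), nrow = 3)
  mm <- toy_markers(vals, tm)
  ll <- dataset_loglik(net, mm, mod11)
  manual <- log(site_likelihood(net,
    site_pattern(names(tm), c(2, 1), c(1, 0), miss = c(1, 0)), mod11))
  expect_equal(ll, manual, tolerance = 1e-12)
  # the integrated likelihood is the sum over completions of the missing entry
  l1 <- site_likelihood(net, site_pattern(names(tm), c(2, 1), c(1, 0)), mod11)
  l2 <- site_likelihood(net, site_pattern(names(tm), c(2, 1), c(2, 0)), mod11)
  expect_equal(exp(ll), l1 + l2, tolerance = 1e-10)
})

test_that("LPL set growth at a reticulation is bounded by the stated quartic rate", {
  set.seed(38)
  net <- rand_network(4, 1)
  sp <- leaf_labels(net)
  counts <- rep(2L, 4)
  M <- sum(counts)
  p <- site_pattern(sp, counts, pmin(counts, 1))
  F <- leaf_partials(2, 1, k = 1, M = M)
  full <- lpl(runif(n_states(M)), 0L)   # dense worst case
  spl <- split_at_reticulation(list(full), 0.4, 0)
  bound <- (n_states(M))^2              # O(n^4) per input LPL
  expect_lte(length(spl$y), bound)
})
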