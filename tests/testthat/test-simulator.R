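mod11 <- mutation_model(1, 1)

test_that("pairwise coalescence time in one population has mean theta/2", {
  set.seed(51)
  theta <- 0.008
  net <- read_rich_newick(sprintf("[%g](A:0:%g);", theta, theta))
  n <- 4000L
  tm <- vapply(seq_len(n), function(i) {
    gt <- sample_gene_tree(net, c(A = 2L))
    max(gt$time)
  }, 0)
  se <- sd(tm) / sqrt(n)
  expect_lt(abs(mean(tm) - theta / 2), 3 * se)
})

test_that("routing fraction at a reticulation matches gamma binomially", {
  # two lineages of one species sit below a reticulation; the gamma-side
  # branch is long with tiny theta (coalescence certain), the other side
  # huge theta (coalescence there is essentially impossible), so the pair
  # coalesces below the root iff both lineages took the gamma edge.
  set.seed(53)
  g <- 0.3
  net <- read_rich_newick(sprintf(paste0(
    "[1e6](((X:0:0.001)H#H1:1:1e-4:%g,A:1:1e6:0):1:1e6,",
    "(H#H1:1:1e6:%g,B:1:1e6:0):1:1e6);"), g, 1 - g))
  n <- 1500L
  both <- 0L
  for (i in seq_len(n)) {
    gt <- sample_gene_tree(net, c(X = 2L, A = 1L, B = 1L))
    # pair coalesced before the root iff some internal node joins the two
    # X lineages at time < 2 (inside the gamma branch)
    xids <- which(!is.na(gt$species) & gt$species == "X")
    anc <- function(id) {
      repeat {
        pa <- which(gt$c1 == id | gt$c2 == id)
        if (!length(pa)) return(integer(0))
        return(c(pa, anc(pa)))
      }
    }
    a1 <- anc(xids[1])
    joined_early <- any(gt$time[a1] < 2 & (gt$c1[a1] %in% xids | gt$c2[a1] %in% xids) &
                          vapply(a1, function(p) all(c(gt$c1[p], gt$c2[p]) %in% xids), TRUE))
    if (joined_early) both <- both + 1L
  }
  phat <- both / n
  se <- sqrt(g^2 * (1 - g^2) / n)
  expect_lt(abs(phat - g^2), 3.5 * se)
})

test_that("gene trees carry one leaf per sampled lineage", {
  set.seed(54)
  net <- example_network("net4_1ret")
  lin <- c(A = 2L, B = 1L, C = 4L, D = 1L)
  gt <- sample_gene_tree(net, lin)
  expect_identical(sum(!is.na(gt$species)), sum(lin))
  expect_identical(length(gt$time), 2L * sum(lin) - 1L)
  tab <- table(gt$species[!is.na(gt$species)])
  expect_identical(as.integer(tab[names(lin)]), as.integer(lin))
  # parent times exceed child times
  for (i in which(!is.na(gt$c1)))
    expect_true(gt$time[i] > max(gt$time[c(gt$c1[i], gt$c2[i])]))
})

test_that("mutation simulation respects stationarity and degenerate rates", {
  set.seed(55)
  net <- read_rich_newick("[0.01](A:0:0.01);")
  gt <- sample_gene_tree(net, c(A = 3L))
  # rate multiplier zero: all leaves share the root state
  cols <- replicate(50, {
    cc <- simulate_site(gt, mod11, rate_multiplier = 0)
    length(unique(cc[!is.na(cc)]))
  })
  expect_true(all(cols == 1))
  # stationary red frequency under u = v = 1 is 1/2
  n <- 4000L
  reds <- vapply(seq_len(n), function(i) {
    gt <- sample_gene_tree(net, c(A = 1L))
    simulate_site(gt, mod11)[1]
  }, 0L)
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(reds) - 0.5), 3 * se)
})

test_that("simulate_bimarkers obeys the polymorphic filter and block structure", {
  set.seed(56)
  net <- example_network("net5_1ret")
  tm <- list(A = "A_0", C = "C_0", L = "L_0", Q = "Q_0", R = "R_0")
  cfg <- sim_config(200, polymorphic_only = TRUE)
  mm <- simulate_bimarkers(net, tm, mod11, cfg)
  poly <- apply(mm$data, 2, function(col) any(col == 1) && any(col == 0))
  expect_true(all(poly))
  expect_true(mm$polymorphic_only)
  # linked blocks draw exactly num_sites / sites_per_genetree gene trees
  cfg2 <- sim_config(100, sites_per_genetree = 10)
  mm2 <- simulate_bimarkers(net, tm, mod11, cfg2)
  expect_identical(attr(mm2, "n_gene_trees"), 10L)
  expect_error(sim_config(105, sites_per_genetree = 10), "divisible")
})

test_that("fixed seeds reproduce the simulated matrix exactly", {
  net <- example_network("net4_1ret")
  tm <- list(A = "a", B = "b", C = c("c1", "c2"), D = "d")
  cfg <- sim_config(50, diploid = TRUE, dominant = TRUE)
  set.seed(77); m1 <- simulate_bimarkers(net, tm, mod11, cfg)
  set.seed(77); m2 <- simulate_bimarkers(net, tm, mod11, cfg)
  expect_identical(m1$data, m2$data)
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  write_marker_tsv(m1, f1); write_marker_tsv(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("diploid and dominant encodings are applied per individual", {
  expect_identical(encode_diploid(c(0L, 0L)), 0L)
  expect_identical(encode_diploid(c(0L, 0L), dominant = TRUE), 0L)
  expect_identical(encode_diploid(c(1L, 0L)), 1L)
  expect_identical(encode_diploid(c(1L, 0L), dominant = TRUE), 1L)
  expect_identical(encode_diploid(c(1L, 1L)), 2L)
  expect_identical(encode_diploid(c(1L, 1L), dominant = TRUE), 1L)
  expect_error(encode_diploid(c(1L, 0L, 1L)), "exactly 2")
  # species-level dominant counts: (1,1),(1,0),(0,0) -> 2 bands of 3
  bands <- c(encode_diploid(c(1L, 1L), TRUE), encode_diploid(c(1L, 0L), TRUE),
             encode_diploid(c(0L, 0L), TRUE))
  expect_identical(sum(bands), 2L)
})

test_that("rate variation draws mean-one multipliers with an invariant class", {
  set.seed(58)
  cfg <- sim_config(10, rate_variation = "markers", inv_prop = 0.2,
                    gamma_shape = 3, n_categories = 4)
  m <- markernet:::draw_rate_multipliers(20000, cfg)
  expect_lt(abs(mean(m == 0) - 0.2), 0.02)
  expect_lt(abs(mean(m[m > 0]) - 1), 0.02)
  means <- markernet:::gamma_category_means(3, 4)
  expect_equal(mean(means), 1, tolerance = 1e-6)
  expect_true(all(diff(means) > 0))
})

test_that("pairwise-difference fractions match the coalescent closed form", {
  # one population, two lineages: P[different colors] =
  # E[ (1 - e^{-2 q t}) / 2 * ... ] with u = v = 1:
  # P(diff) = integral_0^inf (2/theta) e^{-2t/theta} * (1 - e^{-4t})/2 dt
  set.seed(59)
  theta <- 0.01
  net <- read_rich_newick(sprintf("[%g](A:0:%g);", theta, theta))
  q <- 2  # u + v
  # closed form via the integral above
  lam <- 2 / theta
  pdiff_exact <- 0.5 * (1 - lam / (lam + 2 * q))
  n <- 6000L
  diffs <- vapply(seq_len(n), function(i) {
    gt <- sample_gene_tree(net, c(A = 2L))
    cc <- simulate_site(gt, mod11)
    cc <- cc[!is.na(cc)]
    as.integer(cc[1] != cc[2])
  }, 0L)
  se <- sqrt(pdiff_exact * (1 - pdiff_exact) / n)
  expect_lt(abs(mean(diffs) - pdiff_exact), 3 * se)
})

test_that("simulated pattern frequencies match the exact pattern probabilities", {
  set.seed(60)
  net <- rand_network(3, 1)
  sp <- leaf_labels(net)
  tm <- as.list(paste0(tolower(sp), "1")); names(tm) <- sp
  nsites <- 20000L
  mm <- simulate_bimarkers(net, tm, mod11, sim_config(nsites))
  pats <- all_patterns(sp, rep(1L, 3))
  probs <- vapply(pats, function(p) site_likelihood(net, p, mod11), 0)
  keys <- vapply(pats, function(p) paste(vapply(sp, function(s) p[[s]]$red, 1L),
                                         collapse = ""), "")
  obs <- apply(mm$data[unlist(tm)[match(sp, names(tm))], , drop = FALSE], 2,
               paste, collapse = "")
  counts <- table(factor(obs, levels = keys))
  expect_gt(stats::chisq.test(as.integer(counts), p = probs,
                              rescale.p = TRUE)$p.value, 0.001)
})
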