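test_that("rich Newick parsing recovers the 1-reticulation model network", {
  net <- example_network("net5_1ret")
  expect_true(validate_network(net)$ok)
  expect_identical(n_reticulations(net), 1L)
  expect_setequal(leaf_labels(net), c("A", "C", "L", "Q", "R"))
  expect_equal(net$root_theta, 0.006)
  h <- net$ret_index[1]
  g <- sort(net$egamma[which(net$echild == h)])
  expect_equal(g, c(0.3, 0.7))
  # external branches theta 0.006, internal 0.005
  ext <- net$echild %in% leaves(net)
  expect_true(all(net$etheta[ext] == 0.006))
  expect_true(all(net$etheta[!ext] == 0.005))
})

test_that("a plain two-leaf tree parses with no reticulations", {
  net <- read_rich_newick("(A:1.0:0.005,B:1.0:0.005);")
  expect_identical(n_reticulations(net), 0L)
  expect_setequal(leaf_labels(net), c("A", "B"))
  expect_equal(sort(net$elen), c(1, 1))
})

test_that("malformed and inconsistent strings are rejected", {
  expect_error(read_rich_newick("(A:1:0.005,B:1:0.005"), "malformed")
  expect_error(read_rich_newick("(A:1:0.005,A:1:0.005);"), "duplicate")
  expect_error(read_rich_newick(
    "[0.01]((A:1:0.005)X#H1:1:0.005:0.7,(X#H1:1:0.005:0.6,B:2:0.005):1:0.005);"),
    "gamma")
})

test_that("write/parse round-trips preserve the network up to isomorphism", {
  set.seed(11)
  for (i in 1:40) {
    net <- rand_network(sample(3:8, 1), sample(0:3, 1))
    net2 <- read_rich_newick(write_rich_newick(net))
    expect_true(networks_isomorphic(net, net2))
    # gamma pairs still sum to one after the round trip
    for (v in which(net2$kind == 2L)) {
      es <- which(net2$echild == v)
      expect_lt(abs(sum(net2$egamma[es]) - 1), 1e-9)
    }
  }
})

test_that("validate_network reports cycles and time inconsistencies", {
  net <- example_network("net5_1ret")
  expect_true(validate_network(net)$ok)
  # add an edge from a leaf back up to create a directed cycle
  bad <- net
  leafQ <- which(bad$label == "Q")
  bad$eparent <- c(bad$eparent, leafQ)
  bad$echild <- c(bad$echild, bad$root)
  bad$elen <- c(bad$elen, 0.01); bad$etheta <- c(bad$etheta, 0.005)
  bad$egamma <- c(bad$egamma, NA)
  d <- validate_network(bad)
  expect_false(d$ok)
  expect_true(any(grepl("cycle", d$violations)))
  # stretch one branch so two paths to the reticulation disagree
  bad2 <- net
  bad2$elen[1] <- bad2$elen[1] + 0.01
  d2 <- validate_network(bad2)
  expect_false(d2$ok)
  expect_true(any(grepl("time", d2$violations)))
  expect_true(validate_network(bad2, check_times = FALSE)$ok)
})

test_that("child divergence time above its parent's is flagged", {
  net <- rand_ultrametric_tree(3)
  net$times[net$root] <- -1e-3
  d <- validate_network(net)
  expect_false(d$ok)
  expect_true(any(grepl("time", d$violations)))
})

test_that("lowest articulation nodes match the brute-force removal oracle", {
  set.seed(21)
  for (i in 1:25) {
    net <- rand_network(sample(3:6, 1), sample(0:2, 1))
    is_art <- oracle_articulation(net)
    expect_setequal(articulation_nodes(net), which(is_art))
    lows <- which(vapply(seq_along(net$kind), function(v) {
      if (!is_art[v]) return(FALSE)
      ch <- net$echild[net$eparent == v]
      any(!is_art[ch] & net$kind[ch] != 0L)
    }, TRUE))
    expect_setequal(lowest_articulation_nodes(net), lows)
  }
})

test_that("trees have no lowest articulation node", {
  set.seed(3)
  for (i in 1:5)
    expect_length(lowest_articulation_nodes(rand_ultrametric_tree(sample(3:7, 1))), 0L)
})

test_that("a reticulation whose child is a leaf leaves only the root as lowest articulation node", {
  net <- read_rich_newick(paste0(
    "[0.005]((A:0.01:0.005,(L:0.004:0.005)X#H1:0.006:0.005:0.6)",
    ":0.01:0.005,(X#H1:0.008:0.005:0.4,B:0.012:0.005):0.008:0.005);"))
  expect_identical(lowest_articulation_nodes(net), net$root)
})

test_that("reticulation diameter sums the branch lengths on the cycle", {
  net <- example_network("net5_1ret")
  # cycle I5-I3-I2-I1-I4-I5: 0.002 + 0.016 + 0.02 + 0.035 + 0.003
  expect_equal(reticulation_diameter(net, net$ret_index[1]), 0.076)
  # two-edge cycle: reticulation whose parents share one parent
  tiny <- read_rich_newick(paste0(
    "[0.005](((L:0.004:0.005)X#H1:0.006:0.005:0.6,X#H1:0.006:0.005:0.4)",
    ":0.01:0.005,B:0.02:0.005);"))
  expect_equal(reticulation_diameter(tiny, tiny$ret_index[1]), 0.012)
  # rescaling all branch lengths rescales every diameter
  sc <- net
  sc$elen <- sc$elen * 3
  expect_equal(reticulation_diameter(sc, sc$ret_index[1]), 3 * 0.076)
  expect_error(reticulation_diameter(net, leaves(net)[1]), "not a reticulation")
})

test_that("backbone trees drop the minor reticulation edges", {
  net <- example_network("net5_1ret")
  bb <- backbone_tree(net)
  expect_identical(n_reticulations(bb), 0L)
  expect_true(validate_network(bb)$ok)
  ref <- read_rich_newick("(C:1:0.005,((L:1:0.005,(A:1:0.005,Q:1:0.005):1:0.005):1:0.005,R:1:0.005):1:0.005);")
  expect_true(networks_isomorphic(bb, ref))
  expect_equal(rf_distance(bb, ref), 0L)
  bb2 <- backbone_tree(example_network("net5_2ret"))
  ref2 <- read_rich_newick("(C:1:0.005,(R:1:0.005,(L:1:0.005,(A:1:0.005,Q:1:0.005):1:0.005):1:0.005):1:0.005);")
  expect_true(networks_isomorphic(bb2, ref2))
  tr <- rand_ultrametric_tree(4)
  expect_true(networks_isomorphic(backbone_tree(tr), tr))
})

test_that("gamma ties error by default and obey the configured tie-break", {
  tie <- read_rich_newick(paste0(
    "[0.005](((L:0.004:0.005)X#H1:0.006:0.005:0.5,A:0.01:0.005):0.01:0.005,",
    "(X#H1:0.008:0.005:0.5,B:0.012:0.005):0.008:0.005);"))
  expect_error(backbone_tree(tie), "tie")
  bb <- backbone_tree(tie, tie = "postorder")
  expect_identical(n_reticulations(bb), 0L)
  expect_true(validate_network(bb)$ok)
})

test_that("Robinson-Foulds distance counts bipartition differences", {
  t1 <- read_rich_newick("((A:1:0.005,B:1:0.005):1:0.005,(C:1:0.005,D:1:0.005):1:0.005);")
  t2 <- read_rich_newick("((A:1:0.005,C:1:0.005):1:0.005,(B:1:0.005,D:1:0.005):1:0.005);")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  expect_equal(rf_distance(t1, t2), rf_distance(t2, t1))
  t3 <- read_rich_newick("((A:1:0.005,B:1:0.005):1:0.005,(C:1:0.005,E:1:0.005):1:0.005);")
  expect_error(rf_distance(t1, t3), "leaf set")
})

test_that("network isomorphism respects leaf labels and reticulation structure", {
  net <- example_network("net5_1ret")
  # reorder children by re-parsing a child-swapped string
  sw <- read_rich_newick(paste0(
    "[0.006](C:0.08:0.006,((L:0.022:0.006,(A:0.006:0.006,(Q:0.004:0.006)",
    "I5#H1:0.002:0.005:0.7)I3:0.016:0.005)I2:0.02:0.005,(R:0.007:0.006,",
    "I5#H1:0.003:0.005:0.3)I4:0.035:0.005)I1:0.038:0.005);"))
  expect_true(networks_isomorphic(net, sw))
  expect_false(networks_isomorphic(net, example_network("net5_2ret")))
  bb <- backbone_tree(net)
  expect_false(networks_isomorphic(bb, net))
  expect_error(networks_isomorphic(net, rand_ultrametric_tree(3)), "leaf set")
})
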