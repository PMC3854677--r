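test_that("baseline predictor returns the global type rates", {
  ab <- k3_alphabet()
  net <- interaction_network(data.frame(
    drug_a = c("A", "A", "B", "C"), drug_b = c("B", "C", "C", "D"),
    type = c("syn", "syn", "add", "ant")), ab)
  expect_equal(as.numeric(baseline_predict(net)), c(0.5, 0.25, 0.25))
  one <- interaction_network(data.frame(
    drug_a = "A", drug_b = "B", type = "syn"), ab)
  expect_equal(as.numeric(baseline_predict(one)), c(1, 0, 0))
  empty <- interaction_network(NULL, ab, drugs = c("A", "B"))
  expect_error(baseline_predict(empty), "no observed")
  # the baseline does not depend on which pair is queried
  p <- predict_pairs(baseline_predictor(), net,
                     rbind(c("A", "D"), c("B", "D")))
  expect_equal(p[1, ], p[2, ])
})

test_that("interaction similarity counts equal shared reports", {
  ab <- k3_alphabet()
  # A and B share partners C,D,E,F; equal on two of four
  rows <- data.frame(
    drug_a = rep(c("A", "B"), each = 4),
    drug_b = rep(c("C", "D", "E", "F"), 2),
    type = c("syn", "add", "ant", "syn",
             "syn", "add", "syn", "ant"))
  net <- interaction_network(rows, ab)
  expect_equal(interaction_similarity(net, "A", "B"), 0.5)
  # identical profiles over five common partners give similarity 1
  rows2 <- data.frame(
    drug_a = rep(c("X", "Y"), each = 5),
    drug_b = rep(c("C", "D", "E", "F", "G"), 2),
    type = rep(c("syn", "add", "ant", "syn", "add"), 2))
  net2 <- interaction_network(rows2, ab)
  expect_equal(interaction_similarity(net2, "X", "Y"), 1)
  expect_error(interaction_similarity(net, "A", "A"), "itself")
  # shared partners but no equal interaction: defined and zero
  expect_equal(interaction_similarity(net, "C", "D"), 0)
  # drugs with no commonly-reported partner are undefined
  lone <- interaction_network(rbind(rows, data.frame(
    drug_a = "G", drug_b = "H", type = "syn")), ab)
  expect_true(is.na(interaction_similarity(lone, "G", "A")))
})

test_that("neighbor prediction follows the most similar known pair", {
  ab <- k3_alphabet()
  # A2 duplicates A's profile and has a known antagonistic link to B
  rows <- data.frame(
    drug_a = c("A", "A", "A2", "A2", "A2", "C"),
    drug_b = c("C", "D", "C", "D", "B", "D"),
    type = c("syn", "add", "syn", "add", "ant", "syn"))
  net <- interaction_network(rows, ab)
  p <- neighbor_predict(net, c("A", "B"))
  expect_equal(as.numeric(p), c(0, 0, 1))  # predicts antagonistic
  # with no usable similarity structure, fall back to the baseline
  iso <- interaction_network(data.frame(
    drug_a = c("A", "C"), drug_b = c("B", "D"),
    type = c("syn", "ant")), ab)
  expect_equal(neighbor_predict(iso, c("A", "D")), baseline_predict(iso))
})

test_that("neighbor prediction matches the exhaustive-search oracle", {
  for (seed in 1:5) {
    net <- random_net(10, k3_alphabet(), density = 0.6, seed = seed)
    S <- similarity_table(net)
    pairs <- all_pairs(net)
    set.seed(seed)
    for (r in sample(nrow(pairs), 12)) {
      pr <- pairs[r, ]
      expect_equal(neighbor_predict(net, pr, S = S),
                   neighbor_oracle(net, pr),
                   info = paste("seed", seed, "pair", paste(pr, collapse = "-")))
    }
  }
})

test_that("monochromaticity entropy follows the two-type formula", {
  expect_equal(monochromaticity_entropy(c(5, 0)), 0)
  expect_equal(monochromaticity_entropy(c(0, 0)), 0)
  expect_equal(monochromaticity_entropy(c(1, 1)), 2 * log(2))
  expect_equal(monochromaticity_entropy(c(3, 1)),
               4 * (-(3 / 4) * log(3 / 4) - (1 / 4) * log(1 / 4)))
  expect_error(monochromaticity_entropy(c(-1, 2)), "nonnegative")
})

test_that("prism distances complement similarities", {
  ab <- k3_alphabet()
  rows <- data.frame(
    drug_a = rep(c("A", "B"), each = 4),
    drug_b = rep(c("C", "D", "E", "F"), 2),
    type = c("syn", "add", "ant", "syn",
             "syn", "add", "syn", "ant"))
  net <- interaction_network(rows, ab)
  expect_equal(prism_drug_distance(net, "A", "B"), 0.5)
  expect_equal(prism_drug_distance(net, "C", "D"), 1)  # undefined -> 1
})

test_that("prism clustering recovers perfectly monochromatic blocks", {
  # two blocks: within synergistic, between antagonistic (K = 2)
  ab <- type_alphabet(c("syn", "ant"), ordered = TRUE)
  d <- sprintf("m%02d", 1:10)
  g <- rep(1:2, each = 5)
  ij <- combn(10, 2)
  net <- interaction_network(data.frame(
    drug_a = d[ij[1, ]], drug_b = d[ij[2, ]],
    type = ifelse(g[ij[1, ]] == g[ij[2, ]], "syn", "ant")), ab,
    drugs = d)
  tree <- prism_build_tree(net, prism_config())
  expect_equal(nrow(tree$merges), 9L)
  groups <- prism_cut_tree(tree, net, prism_config())
  expect_equal(length(unique(groups)), 2L)
  expect_true(all(tapply(g, groups, function(x) length(unique(x))) == 1))
  # the first N - 2 merges never mix the two blocks
  # (checked via the cut partition being exactly the planted one)
  # duplicate drugs merge first: distance 0 at the first step
  expect_equal(tree$merges$distance[1], 0)
})

test_that("prism tree cutting respects the entropy threshold", {
  ab <- type_alphabet(c("syn", "ant"), ordered = TRUE)
  d <- sprintf("m%02d", 1:8)
  g <- rep(1:2, each = 4)
  ij <- combn(8, 2)
  net <- interaction_network(data.frame(
    drug_a = d[ij[1, ]], drug_b = d[ij[2, ]],
    type = ifelse(g[ij[1, ]] == g[ij[2, ]], "syn", "ant")), ab, drugs = d)
  tree <- prism_build_tree(net, prism_config())
  # threshold 1: the single-group partition trivially qualifies
  g1 <- prism_cut_tree(tree, net, prism_config(cut_threshold = 1))
  expect_equal(length(unique(g1)), 1L)
  # at threshold 0 on a network where every two-drug merge mixes types,
  # only the all-singletons partition (entropy 0 by construction)
  # qualifies
  ab2 <- type_alphabet(c("syn", "ant"), ordered = TRUE)
  frustrated <- interaction_network(data.frame(
    drug_a = c("A", "A", "A", "B", "B", "C"),
    drug_b = c("B", "C", "D", "C", "D", "D"),
    type = c("ant", "syn", "ant", "ant", "syn", "syn")), ab2)
  ftree <- prism_build_tree(frustrated, prism_config())
  gs <- prism_cut_tree(ftree, frustrated, prism_config(cut_threshold = 0))
  expect_equal(length(unique(gs)), 4L)
})

test_that("prism estimator equals the single-partition block-model one", {
  net <- two_block_net()
  groups <- setNames(rep(1:2, each = 3), net$drugs)
  s <- single_partition_samples(net, groups)
  for (pair in list(c("A", "B"), c("A", "D"), c("C", "F"))) {
    expect_equal(prism_predict(net, groups, pair),
                 link_type_posterior(s, pair))
  }
  # a group pair with no observations gives the uniform vector
  empty <- interaction_network(NULL, k3_alphabet(), drugs = LETTERS[1:4])
  expect_equal(as.numeric(prism_predict(empty, c(1, 1, 2, 2),
                                        c("A", "C"))), rep(1 / 3, 3))
  # Laplace smoothing: counts (3, 0) at K = 2 give (4/5, 1/5)
  ab2 <- type_alphabet(c("syn", "ant"), ordered = TRUE)
  n2 <- interaction_network(data.frame(
    drug_a = c("A", "A", "B"), drug_b = c("C", "D", "C"), type = "syn"),
    ab2)
  p <- prism_predict(n2, setNames(c(1, 1, 2, 2),
                                  c("A", "B", "C", "D")), c("A", "C"),
                     exclude_self = FALSE)
  expect_equal(as.numeric(p), c(4 / 5, 1 / 5))
})
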