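test_that("the pair factor matches its closed form on small cases", {
  expect_equal(log_pair_factor(c(0, 0)), 0)
  expect_equal(log_pair_factor(c(0, 0, 0)), 0)
  expect_equal(log_pair_factor(c(1, 0)), log(1 / 2))
  expect_equal(log_pair_factor(c(1, 1, 0)), log(1 / 12))
  expect_error(log_pair_factor(c(-1, 2)), "negative")
  expect_error(log_pair_factor(3), "K >= 2")
  # the switch drops exactly the log((K-1)!) constant
  expect_equal(log_pair_factor(c(2, 1), include_prior_constant = FALSE),
               log_pair_factor(c(2, 1)) - lgamma(2))
  expect_equal(log_pair_factor(c(2, 1, 1), include_prior_constant = FALSE),
               log_pair_factor(c(2, 1, 1)) - lgamma(3))
})

test_that("H rewards partitions that explain interaction types", {
  net <- two_block_net(hold_out = NULL)
  blocks <- rep(1:2, each = 3)
  # block partition beats a scrambled partition of the same sizes
  expect_lt(compute_H(net, blocks), compute_H(net, c(1, 2, 1, 2, 1, 2)))
  # and beats the single-group and singleton partitions
  expect_lt(compute_H(net, blocks), compute_H(net, rep(1, 6)))
  expect_lt(compute_H(net, blocks), compute_H(net, 1:6))
  # a network with no observations has H = 0 for every partition
  empty <- interaction_network(NULL, k3_alphabet(), drugs = LETTERS[1:4])
  expect_equal(compute_H(empty, c(1, 1, 2, 2)), 0)
  expect_equal(compute_H(empty, rep(1, 4)), 0)
})

test_that("incremental H bookkeeping agrees with full recomputation", {
  net <- two_block_net()
  raw <- metropolis_chain(net, 300, seed = 3)
  H_scratch <- vapply(seq_len(300), function(r) {
    compute_H(net, raw$assign[r, ] + 1L)
  }, 0.0)
  expect_lt(max(abs(H_scratch - raw$H)), 1e-10)
  # same agreement without the prior constant
  raw2 <- metropolis_chain(net, 100, seed = 4,
                           include_prior_constant = FALSE)
  H2 <- vapply(seq_len(100), function(r) {
    compute_H(net, raw2$assign[r, ] + 1L, include_prior_constant = FALSE)
  }, 0.0)
  expect_lt(max(abs(H2 - raw2$H)), 1e-10)
})

test_that("seeded sampler runs are bit-reproducible", {
  net <- two_block_net()
  cfg <- sampler_config(n_chains = 3, samples_per_chain = 20, seed = 99)
  s1 <- run_sampler(net, cfg)
  s2 <- run_sampler(net, cfg)
  expect_identical(s1$assign, s2$assign)
  expect_identical(s1$H, s2$H)
  s3 <- run_sampler(net, sampler_config(n_chains = 3,
                                        samples_per_chain = 20, seed = 100))
  expect_false(identical(s1$assign, s3$assign))
})

test_that("pooled sample count follows the configuration", {
  net <- two_block_net()
  s <- run_sampler(net, sampler_config(n_chains = 4,
                                       samples_per_chain = 30, seed = 2))
  expect_equal(nrow(s$assign), 4L * 30L)
  expect_equal(length(s$H), 120L)
})

test_that("an empty network gives uniform posteriors and H = 0", {
  empty <- interaction_network(NULL, k3_alphabet(), drugs = LETTERS[1:5])
  s <- run_sampler(empty, sampler_config(n_chains = 1,
                                         samples_per_chain = 5, seed = 1))
  expect_equal(unique(s$H), 0)
  p <- link_type_posterior(s, c("A", "B"))
  expect_equal(as.numeric(p), rep(1 / 3, 3))
})

test_that("posteriors are normalized and complete over all pairs", {
  net <- random_net(9, k3_alphabet(), density = 0.5, seed = 7)
  scores <- score_all_pairs(net, sampler_config(n_chains = 5,
                                                samples_per_chain = 50,
                                                seed = 3))
  expect_equal(nrow(scores), choose(9, 2))
  p <- as.matrix(scores[, 3:5])
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(link_type_posterior(attr(scores, "samples"),
                                   c("r01", "nope")), "unknown drug")
})

test_that("posterior concentrates when all observations share one type", {
  d <- sprintf("x%d", 1:7)
  ij <- combn(7, 2)
  net <- interaction_network(
    data.frame(drug_a = d[ij[1, ]], drug_b = d[ij[2, ]], type = "syn"),
    k3_alphabet())
  # hold one pair out and predict it
  held <- net
  held$obs <- net$obs[-1, ]
  s <- run_sampler(held, sampler_config(n_chains = 5,
                                        samples_per_chain = 100, seed = 5))
  p <- link_type_posterior(s, c(net$obs$a[1], net$obs$b[1]))
  expect_gt(p[["syn"]], 0.8)
})

test_that("renaming drugs leaves sampler output identical", {
  net <- two_block_net()
  renamed <- net
  renamed$drugs <- paste0("drug_", net$drugs)
  renamed$obs$a <- paste0("drug_", net$obs$a)
  renamed$obs$b <- paste0("drug_", net$obs$b)
  cfg <- sampler_config(n_chains = 3, samples_per_chain = 30, seed = 17)
  p1 <- link_type_posterior(run_sampler(net, cfg), c("A", "B"))
  p2 <- link_type_posterior(run_sampler(renamed, cfg),
                            c("drug_A", "drug_B"))
  expect_equal(as.numeric(p1), as.numeric(p2))
})

test_that("exact posterior is invariant under drug permutations", {
  net <- two_block_net()
  ex1 <- exact_link_posterior(net, c("A", "B"))
  perm <- c(4L, 6L, 1L, 3L, 2L, 5L)
  net2 <- net
  net2$drugs <- net$drugs[perm]
  net2 <- interaction_network(
    data.frame(drug_a = net$obs$a, drug_b = net$obs$b,
               type = net$alphabet$labels[net$obs$type]),
    net$alphabet, drugs = net2$drugs)
  ex2 <- exact_link_posterior(net2, c("A", "B"))
  expect_equal(as.numeric(ex1), as.numeric(ex2), tolerance = 1e-12)
})

test_that("more consistent evidence raises the posterior of that type", {
  # two fixed groups; increasing antagonistic counts between them pushes
  # the held-out between-group pair toward antagonistic
  ab <- k3_alphabet()
  build <- function(n_between) {
    d <- LETTERS[1:6]
    g <- rep(1:2, each = 3)
    rows <- list()
    for (i in 1:5) for (j in (i + 1):6) {
      if (g[i] == g[j]) {
        rows[[length(rows) + 1L]] <-
          data.frame(drug_a = d[i], drug_b = d[j], type = "syn")
      }
    }
    between <- which(outer(g, g, "!="), arr.ind = TRUE)
    between <- between[between[, 1] < between[, 2], , drop = FALSE]
    between <- between[-1, , drop = FALSE]   # hold out the first
    for (r in seq_len(min(n_between, nrow(between)))) {
      rows[[length(rows) + 1L]] <- data.frame(
        drug_a = d[between[r, 1]], drug_b = d[between[r, 2]],
        type = "ant")
    }
    interaction_network(do.call(rbind, rows), ab)
  }
  held <- c("A", "D")
  p_ant <- vapply(c(1, 4, 8), function(m) {
    exact_link_posterior(build(m), held)[1, "ant"]
  }, 0.0)
  expect_true(all(diff(p_ant) > 0))
})

test_that("co-classification matrices behave like posteriors", {
  net <- two_block_net()
  # a single-sample set gives the indicator matrix of that partition
  g <- c(1, 1, 1, 2, 2, 2)
  s1 <- single_partition_samples(net, g)
  cc1 <- coclassification_matrix(s1)
  expect_equal(unname(cc1), outer(g, g, "==") + 0)
  # sampled co-classification approximates the exact one
  s <- run_sampler(net, sampler_config(n_chains = 10,
                                       samples_per_chain = 100, seed = 23))
  cc <- coclassification_matrix(s)
  exact <- exact_coclassification(net)
  expect_lt(max(abs(cc - exact)), 0.05)
  expect_equal(diag(cc), setNames(rep(1, 6), net$drugs))
  expect_equal(cc, t(cc))
})

test_that("duplicate-profile drugs co-classify at least as much as others", {
  # E and F have identical interaction profiles by construction
  ab <- k3_alphabet()
  rows <- data.frame(
    drug_a = c("A", "A", "B", "A", "B", "C", "A", "B", "C"),
    drug_b = c("B", "C", "C", "E", "E", "E", "F", "F", "F"),
    type = c("syn", "syn", "syn", "ant", "ant", "syn",
             "ant", "ant", "syn"))
  net <- interaction_network(rows, ab)
  cc <- exact_coclassification(net)
  others <- setdiff(net$drugs, c("E", "F"))
  expect_true(all(cc["E", "F"] >= cc["E", others]))
  expect_true(all(cc["E", "F"] >= cc["F", others]))
})

test_that("strict mode surfaces thermalization failures", {
  net <- random_net(10, k3_alphabet(), density = 0.9, seed = 2)
  cfg <- sampler_config(n_chains = 1, samples_per_chain = 2, seed = 1,
                        therm_window = 5, therm_cap = 6, strict = TRUE)
  expect_error(run_sampler(net, cfg), "equilibration")
  cfg$strict <- FALSE
  expect_warning(run_sampler(net, cfg), "equilibration")
})
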