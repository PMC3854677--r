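# Shared fixtures and independent oracles, all built in code.

k3_alphabet <- function() {
  type_alphabet(c("syn", "add", "ant"), ordered = TRUE)
}

k4_alphabet <- function() {
  type_alphabet(c("syn", "add", "ant", "sup"), ordered = TRUE)
}

# 6-drug two-block toy: within-block synergistic, between-block
# antagonistic; optionally one pair held out
two_block_net <- function(hold_out = c("A", "B")) {
  d <- LETTERS[1:6]
  g <- rep(1:2, each = 3)
  rows <- list()
  for (i in 1:5) for (j in (i + 1):6) {
    rows[[length(rows) + 1L]] <- data.frame(
      drug_a = d[i], drug_b = d[j],
      type = if (g[i] == g[j]) "syn" else "ant")
  }
  edges <- do.call(rbind, rows)
  if (!is.null(hold_out)) {
    edges <- edges[!(edges$drug_a == hold_out[1] &
                       edges$drug_b == hold_out[2]), ]
  }
  interaction_network(edges, k3_alphabet())
}

# small 5-drug binary-typed network for stationary-distribution checks
five_drug_net <- function() {
  interaction_network(data.frame(
    drug_a = c("A", "A", "B", "C", "D"),
    drug_b = c("B", "C", "C", "D", "E"),
    type = c("syn", "syn", "syn", "ant", "ant")),
    type_alphabet(c("syn", "ant"), ordered = TRUE))
}

# planted K=3 model at the recovery-benchmark conditions: 60 drugs in 3
# equal groups, one dominant type per group pair with probability 0.9
planted_k3_model <- function() {
  theta <- function(a, b) {
    th <- rep(0.05, 3)
    th[(a + b - 2L) %% 3L + 1L] <- 0.9
    th
  }
  planted_model(c(20L, 20L, 20L), k3_alphabet(), theta)
}

# planted binary model at the snapshot/discovery-benchmark conditions:
# 100 drugs in 4 equal groups, strongly assortative link densities
planted_binary_model <- function() {
  theta <- function(a, b) if (a == b) c(0.3, 0.7) else c(0.97, 0.03)
  planted_model(rep(25L, 4L), binary_alphabet(), theta)
}

# rewire one drug of a generated binary network to exactly `degree` true
# partners drawn with the planted block probabilities
rewire_target <- function(gen, target, degree, seed) {
  set.seed(seed)
  net <- gen$net
  others <- setdiff(net$drugs, target)
  w <- ifelse(gen$groups[others] == gen$groups[target], 0.7, 0.03)
  partners <- sample(others, degree, prob = w)
  obs <- net$obs[net$obs$a != target & net$obs$b != target, , drop = FALSE]
  obs <- rbind(obs, data.frame(a = pmin(target, partners),
                               b = pmax(target, partners), type = 2L))
  obs <- obs[order(obs$a, obs$b), ]
  rownames(obs) <- NULL
  net$obs <- obs
  list(net = net, partners = partners)
}

# --- independent oracles -----------------------------------------------

# Monte-Carlo integration of the Dirichlet pair factor: the marginal
# likelihood equals E[prod_k p_k^{n_k}] under uniform p on the simplex
mc_pair_factor <- function(counts, n_draws = 1e6, seed = 1) {
  set.seed(seed)
  K <- length(counts)
  g <- matrix(rgamma(n_draws * K, shape = 1), ncol = K)
  p <- g / rowSums(g)
  mean(exp(log(p) %*% counts))
}

# quadrature for K = 2: int_0^1 p^a (1-p)^b dp
quad_pair_factor <- function(a, b) {
  integrate(function(p) p^a * (1 - p)^b, 0, 1,
            rel.tol = 1e-10)$value
}

# exhaustive neighbor-based prediction: scan every ordered candidate pair
# (k, l) with a known interaction, score S_ik * S_jl (self-similarity 1),
# same tie rules, independent of the package's vectorized path
neighbor_oracle <- function(net, pair) {
  tm <- type_matrix(net)
  d <- net$drugs
  ii <- match(pair[1], d); jj <- match(pair[2], d)
  tm[ii, jj] <- tm[jj, ii] <- NA
  simil <- function(x, y) {
    if (x == y) return(1)
    z <- setdiff(seq_along(d), c(x, y))
    both <- z[!is.na(tm[x, z]) & !is.na(tm[y, z])]
    if (!length(both)) return(NA_real_)
    mean(tm[x, both] == tm[y, both])
  }
  best <- NULL
  for (k in seq_along(d)) for (l in seq_along(d)) {
    if (k == l || is.na(tm[k, l])) next
    sik <- simil(ii, k); sjl <- simil(jj, l)
    if (is.na(sik) || is.na(sjl)) next
    pr <- sik * sjl
    if (pr <= 0) next
    cand <- list(pr = pr, mn = min(sik, sjl), k = k, l = l,
                 type = tm[k, l])
    if (is.null(best) || pr > best$pr + 1e-12 ||
        (abs(pr - best$pr) <= 1e-12 &&
         (cand$mn > best$mn + 1e-12 ||
          (abs(cand$mn - best$mn) <= 1e-12 &&
           (k < best$k || (k == best$k && l < best$l)))))) {
      best <- cand
    }
  }
  if (is.null(best)) return(baseline_predict(net))
  out <- numeric(net$alphabet$K)
  out[best$type] <- 1
  setNames(out, net$alphabet$labels)
}

# brute-force AUROC by pair counting
auroc_brute <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  wins / (length(pos) * length(neg))
}

# random typed network for property checks
random_net <- function(n, alphabet, density = 0.7, seed = 1) {
  set.seed(seed)
  d <- sprintf("r%02d", seq_len(n))
  ij <- combn(n, 2L)
  keep <- runif(ncol(ij)) < density
  edges <- data.frame(
    drug_a = d[ij[1L, keep]], drug_b = d[ij[2L, keep]],
    type = sample(alphabet$labels, sum(keep), replace = TRUE))
  interaction_network(edges, alphabet, drugs = d)
}

# sbm_samples object pinned to a single fixed partition
single_partition_samples <- function(net, groups) {
  view <- ddiblock:::sbm_view(net, "heldout")
  structure(list(assign = matrix(as.integer(groups) - 1L, nrow = 1L),
                 H = 0, chain = 1L, burnin = 0L, thinning = 1L,
                 thermalized = TRUE, view = view, drugs = net$drugs,
                 alphabet = net$alphabet,
                 config = sampler_config(n_chains = 1L,
                                         samples_per_chain = 1L),
                 mode = "heldout"),
            class = "sbm_samples")
}
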