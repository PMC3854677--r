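#' Log marginal likelihood of one group pair's type counts
#'
#' For a pair of drug groups with `n^k` observed interactions of each of
#' the K types (`n = sum(n^k)`), the group-to-group type-probability vector
#' is integrated out under a uniform prior on the K-simplex, giving the
#' closed-form marginal likelihood
#' \deqn{(K-1)!\, \prod_k n^k! \,/\, (n+K-1)!}
#' This is the factor contributed by each group pair to the evidence of a
#' partition; the partition's `H` is minus the sum of these log factors.
#'
#' @param type_counts nonnegative integer vector of length K >= 2.
#' @param include_prior_constant logical; include the `log((K-1)!)`
#'   prior-density constant (the exact Dirichlet marginal).  The constant
#'   does not cancel between partitions with different group counts, so it
#'   is exposed as a switch; the default includes it.
#' @return the log factor (0 for all-zero counts when the constant is
#'   included).
#' @examples
#' log_pair_factor(c(1, 0))     # log(1/2)
#' log_pair_factor(c(1, 1, 0))  # log(1/12)
#' @export
log_pair_factor <- function(type_counts, include_prior_constant = TRUE) {
  if (length(type_counts) < 2L) stop("K >= 2 required")
  if (any(type_counts < 0)) stop("negative count")
  K <- length(type_counts)
  n <- sum(type_counts)
  val <- sum(lgamma(type_counts + 1)) - lgamma(n + K)
  if (include_prior_constant) val <- val + lgamma(K)
  val
}

#' Partition weight H
#'
#' `H` is minus the log of the marginalized likelihood of a partition:
#' the sum over all unordered group pairs (within-group pairs included) of
#' minus [log_pair_factor()] of that pair's type counts.  Lower `H` means
#' higher explanatory power; the Bayesian model average weights each
#' partition by `exp(-H)`.  Computed from scratch in R (the sampler keeps
#' `H` incrementally in compiled code; the two must agree).
#'
#' @param net an [interaction_network()].
#' @param groups integer vector of group labels, one per drug of `net`
#'   (any labels; only the induced partition matters).
#' @param mode `"heldout"` (unobserved pairs contribute no counts) or
#'   `"fully_observed"` (binary networks: every pair is an observation,
#'   absence = "none").
#' @param include_prior_constant see [log_pair_factor()].
#' @return the scalar H.
#' @export
compute_H <- function(net, groups, mode = c("heldout", "fully_observed"),
                      include_prior_constant = TRUE) {
  mode <- match.arg(mode)
  view <- sbm_view(net, mode)
  stopifnot(length(groups) == length(net$drugs))
  counts <- partition_counts(view, groups)
  -sum(vapply(counts, log_pair_factor, 0.0,
              include_prior_constant = include_prior_constant))
}

# group-pair type-count vectors for an edge view and an assignment;
# returns a list over occupied group pairs (alpha <= beta), each a
# length-K count vector (cells with no occupied drugs are omitted; with
# the prior constant included they contribute 0 to H, and without it the
# C++ core adds the matching lgamma(K) per cell of occupied-group pairs,
# which compute_H reproduces by including empty occupied cells)
partition_counts <- function(view, groups) {
  groups <- as.integer(factor(groups))
  b <- max(groups)
  K <- view$K
  cells <- vector("list", b * (b + 1L) / 2L)
  idx <- function(a, g) (a - 1L) * (b + 1L) - (a * (a - 1L)) %/% 2L + g - a + 1L
  for (a in seq_len(b)) for (g in a:b) {
    cells[[idx(a, g)]] <- integer(K)
  }
  if (nrow(view$edges)) {
    ga <- groups[view$edges[, 1L] + 1L]
    gb <- groups[view$edges[, 2L] + 1L]
    lo <- pmin(ga, gb); hi <- pmax(ga, gb)
    ty <- view$edges[, 3L] + 1L
    for (e in seq_along(lo)) {
      i <- idx(lo[e], hi[e])
      cells[[i]][ty[e]] <- cells[[i]][ty[e]] + 1L
    }
  }
  cells
}

# Build the edge view the sampler conditions on.  heldout: only stored
# observations are counts.  fully_observed: binary networks where every
# pair of drugs is an observation -- stored pairs with their stored type,
# absent pairs as type "none" (index 0).
sbm_view <- function(net, mode = c("heldout", "fully_observed")) {
  mode <- match.arg(mode)
  N <- length(net$drugs)
  K <- net$alphabet$K
  if (mode == "heldout") {
    edges <- edge_matrix(net)
  } else {
    if (!is_binary_alphabet(net$alphabet))
      stop("fully_observed mode requires the binary none/interaction alphabet")
    ij <- combn(N, 2L)
    tm <- type_matrix(net)
    ty <- tm[cbind(ij[1L, ], ij[2L, ])]
    ty[is.na(ty)] <- 1L   # unstored pair = "none"
    edges <- cbind(ij[1L, ] - 1L, ij[2L, ] - 1L, ty - 1L)
  }
  storage.mode(edges) <- "integer"
  list(edges = edges, N = N, K = K, mode = mode)
}

#' Sampler configuration
#'
#' Defaults reproduce the sampling protocol used throughout: 50
#' independent chains of 200 recorded partitions each (10,000 pooled
#' samples), each chain starting from an independent uniformly random
#' assignment, discarding a burn-in determined by an equilibration test on
#' `H` and recording one partition per automatically chosen thinning
#' interval (one interval = the estimated decorrelation time of `H`, in
#' sweeps of N elementary moves).
#'
#' @param n_chains number of independent chains.
#' @param samples_per_chain recorded partitions per chain.
#' @param seed integer seed; all randomness of a run derives from it.
#' @param thinning fixed thinning interval in sweeps, or NULL to estimate
#'   it from the autocorrelation of `H`.
#' @param therm_window window length (sweeps) of the equilibration test:
#'   a chain is considered thermalized when the means of `H` over two
#'   consecutive windows differ by less than one pooled standard error.
#' @param therm_cap maximum burn-in sweeps before giving up on the test.
#' @param probe_sweeps sweeps used to estimate the decorrelation time.
#' @param thin_cap upper bound on the automatic thinning interval.
#' @param include_prior_constant see [log_pair_factor()].
#' @param strict if TRUE, a chain that fails the equilibration test within
#'   `therm_cap` sweeps is an error; otherwise a warning and the chain
#'   proceeds.
#' @return a `sampler_config` object.
#' @export
sampler_config <- function(n_chains = 50L, samples_per_chain = 200L,
                           seed = 1L, thinning = NULL,
                           therm_window = 20L, therm_cap = 10000L,
                           probe_sweeps = 200L, thin_cap = 50L,
                           include_prior_constant = TRUE, strict = FALSE) {
  stopifnot(n_chains >= 1L, samples_per_chain >= 1L)
  structure(list(n_chains = as.integer(n_chains),
                 samples_per_chain = as.integer(samples_per_chain),
                 seed = as.integer(seed),
                 thinning = if (is.null(thinning)) 0L else as.integer(thinning),
                 therm_window = as.integer(therm_window),
                 therm_cap = as.integer(therm_cap),
                 probe_sweeps = as.integer(probe_sweeps),
                 thin_cap = as.integer(thin_cap),
                 include_prior_constant = isTRUE(include_prior_constant),
                 strict = isTRUE(strict)),
            class = "sampler_config")
}

#' Sample partitions by the Metropolis algorithm
#'
#' Runs independent Markov chains over partitions of the drugs, each
#' proposing single-drug moves to one of the other `N - 1` group labels
#' and accepting so that the stationary distribution over set partitions
#' is `exp(-H)/Z` (an occupied-group multiplicity correction makes the
#' label representation exact; see the methods vignette).  Each chain
#' burns in until the equilibration test passes, then records
#' `samples_per_chain` partitions separated by the thinning interval;
#' samples are pooled across chains.
#'
#' @param net an [interaction_network()].
#' @param config a [sampler_config()].
#' @param mode observation semantics, see [compute_H()].
#' @return An object of class `sbm_samples`: list with `assign` (samples x
#'   drugs matrix of 0-based group labels), `H`, `chain`, per-chain
#'   `burnin`, `thinning` and `thermalized`, plus the network view.
#' @export
run_sampler <- function(net, config = sampler_config(),
                        mode = c("heldout", "fully_observed")) {
  mode <- match.arg(mode)
  view <- sbm_view(net, mode)
  res <- sbm_sampler_cpp(view$N, view$edges, view$K,
                         config$n_chains, config$samples_per_chain,
                         as.double(config$seed), config$thinning,
                         config$therm_window, config$therm_cap,
                         config$probe_sweeps, config$thin_cap,
                         config$include_prior_constant)
  if (!all(res$thermalized)) {
    msg <- sprintf("%d of %d chains failed the equilibration test within %d sweeps",
                   sum(!res$thermalized), config$n_chains, config$therm_cap)
    if (config$strict) stop(msg) else warning(msg)
  }
  structure(list(assign = res$assign, H = res$H, chain = res$chain,
                 burnin = res$burnin, thinning = res$thinning,
                 thermalized = res$thermalized, view = view,
                 drugs = net$drugs, alphabet = net$alphabet,
                 config = config, mode = mode),
            class = "sbm_samples")
}

#' @export
print.sbm_samples <- function(x, ...) {
  cat("SBM partition samples:", nrow(x$assign), "pooled samples (",
      x$config$n_chains, "chains x", x$config$samples_per_chain,
      "), mode =", x$mode, "\n")
  cat("  thinning (sweeps):", paste(range(x$thinning), collapse = "-"),
      "; burn-in (sweeps):", paste(range(x$burnin), collapse = "-"), "\n")
  invisible(x)
}

#' Raw diagnostic chain
#'
#' Runs a single chain and records the partition at the end of every
#' sweep, with no equilibration test and no thinning.  Used for
#' stationary-distribution diagnostics on tiny networks.
#'
#' @inheritParams run_sampler
#' @param n_sweeps recorded sweeps.
#' @param burnin_sweeps sweeps discarded before recording.
#' @param seed integer seed.
#' @param include_prior_constant see [log_pair_factor()].
#' @return list with `assign` (n_sweeps x N matrix) and `H`.
#' @export
metropolis_chain <- function(net, n_sweeps, burnin_sweeps = 0L, seed = 1L,
                             mode = c("heldout", "fully_observed"),
                             include_prior_constant = TRUE) {
  mode <- match.arg(mode)
  view <- sbm_view(net, mode)
  sbm_raw_chain_cpp(view$N, view$edges, view$K, as.integer(n_sweeps),
                    as.integer(burnin_sweeps), as.double(seed),
                    include_prior_constant)
}

# resolve a pair given as names or indices to 1-based indices
resolve_pair <- function(drugs, pair) {
  if (is.character(pair)) {
    idx <- match(pair, drugs)
    if (anyNA(idx))
      stop("unknown drug(s): ", paste(pair[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(pair)
    stopifnot(all(idx >= 1L), all(idx <= length(drugs)))
  }
  if (idx[1L] == idx[2L]) stop("a pair must consist of two distinct drugs")
  idx
}

#' Posterior type probabilities for a drug pair
#'
#' Averages, over the pooled sampled partitions, the per-partition
#' estimator `(n^k + 1) / (n + K)` evaluated at the group pair of the two
#' drugs, where `n^k` and `n` are the type counts between those groups.
#' Because partitions are sampled proportionally to `exp(-H)`, the plain
#' sample average estimates the Bayesian model average over all
#' partitions.  In fully-observed mode the pair's own observation is
#' removed from the counts before evaluating the estimator.
#'
#' @param samples an `sbm_samples` object from [run_sampler()].
#' @param pair length-2 vector of drug names (or indices).
#' @return normalized numeric vector of length K, named by type labels.
#' @export
link_type_posterior <- function(samples, pair) {
  idx <- resolve_pair(samples$drugs, pair)
  qt <- pair_view_types(samples$view, idx[1L], idx[2L])
  p <- sbm_posterior_cpp(samples$assign, samples$view$edges,
                         samples$view$N, samples$view$K,
                         idx[1L] - 1L, idx[2L] - 1L, qt)
  setNames(as.numeric(p[1L, ]), samples$alphabet$labels)
}

# 0-based observed type of pairs under the view (-1 if unobserved or
# heldout mode: no exclusion correction outside fully_observed mode)
pair_view_types <- function(view, qi, qj) {
  if (view$mode != "fully_observed") return(rep(-1L, length(qi)))
  N <- view$N
  tm <- matrix(-1L, N, N)
  e <- view$edges
  tm[cbind(e[, 1L] + 1L, e[, 2L] + 1L)] <- e[, 3L]
  tm[cbind(e[, 2L] + 1L, e[, 1L] + 1L)] <- e[, 3L]
  as.integer(tm[cbind(qi, qj)])
}

#' Score every drug pair of a network
#'
#' One sampler run scores all `choose(N, 2)` pairs (observed and
#' unobserved) with [link_type_posterior()]; in fully-observed mode the
#' per-pair leave-own-observation-out correction is applied.
#'
#' @inheritParams run_sampler
#' @param samples optionally, an existing `sbm_samples` object to reuse
#'   instead of running the sampler (its mode must match `mode`).
#' @return data frame with columns `drug_a`, `drug_b` and one probability
#'   column `p_<label>` per type.
#' @export
score_all_pairs <- function(net, config = sampler_config(),
                            mode = c("heldout", "fully_observed"),
                            samples = NULL) {
  mode <- match.arg(mode)
  if (is.null(samples)) {
    samples <- run_sampler(net, config, mode)
  } else {
    stopifnot(inherits(samples, "sbm_samples"), samples$mode == mode)
  }
  N <- length(net$drugs)
  ij <- combn(N, 2L)
  qt <- pair_view_types(samples$view, ij[1L, ], ij[2L, ])
  p <- sbm_posterior_cpp(samples$assign, samples$view$edges, N,
                         samples$view$K, ij[1L, ] - 1L, ij[2L, ] - 1L, qt)
  out <- data.frame(drug_a = net$drugs[ij[1L, ]],
                    drug_b = net$drugs[ij[2L, ]])
  p <- as.data.frame(p)
  names(p) <- paste0("p_", net$alphabet$labels)
  out <- cbind(out, p)
  attr(out, "samples") <- samples
  out
}

#' Co-classification probabilities
#'
#' Fraction of pooled sampled partitions in which each pair of drugs
#' shares a group; a posterior probability of co-membership.  Symmetric,
#' with unit diagonal.
#'
#' @param samples an `sbm_samples` object.
#' @return N x N numeric matrix with drug names as dimnames.
#' @export
coclassification_matrix <- function(samples) {
  stopifnot(inherits(samples, "sbm_samples"), nrow(samples$assign) > 0L)
  m <- sbm_coclass_cpp(samples$assign)
  dimnames(m) <- list(samples$drugs, samples$drugs)
  m
}

#' Write pair predictions as TSV
#'
#' @param scores data frame from [score_all_pairs()] (or any predictor's
#'   pair-probability table).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
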