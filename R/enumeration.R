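#' All set partitions of n elements
#'
#' Enumerates the Bell(n) partitions as restricted growth strings: row `r`
#' is an assignment where element 1 is in group 1 and each element's label
#' is at most one more than the maximum label before it.  Intended for
#' exact sums on tiny networks (n <= 10).
#'
#' @param n number of elements (2..10).
#' @return integer matrix, one partition per row.
#' @export
set_partitions <- function(n) {
  stopifnot(n >= 1L, n <= 10L)
  rows <- list(c(1L))
  for (el in seq_len(n - 1L)) {
    nxt <- vector("list", 0L)
    for (r in rows) {
      m <- max(r)
      for (g in seq_len(m + 1L)) nxt[[length(nxt) + 1L]] <- c(r, g)
    }
    rows <- nxt
  }
  do.call(rbind, rows)
}

#' Exact posterior over partitions on tiny networks
#'
#' Computes the Bayesian model average exactly by summing the per-pair
#' estimator `(n^k + 1)/(n + K)` over all set partitions of the drugs,
#' each weighted by `exp(-H)`.  This is the quantity the Metropolis
#' sampler estimates; it is tractable only for small drug sets
#' (Bell(8) = 4140 partitions).
#'
#' @param net an [interaction_network()] with at most 10 drugs.
#' @param pairs two-column matrix of drug names (or a length-2 vector for
#'   a single pair).
#' @param mode observation semantics, see [compute_H()].
#' @param include_prior_constant see [log_pair_factor()].
#' @return matrix of posterior type probabilities, one row per pair,
#'   columns named by type labels.
#' @export
exact_link_posterior <- function(net, pairs,
                                 mode = c("heldout", "fully_observed"),
                                 include_prior_constant = TRUE) {
  mode <- match.arg(mode)
  if (is.null(dim(pairs))) pairs <- matrix(pairs, nrow = 1L)
  N <- length(net$drugs)
  K <- net$alphabet$K
  view <- sbm_view(net, mode)
  parts <- set_partitions(N)
  qi <- match(pairs[, 1L], net$drugs)
  qj <- match(pairs[, 2L], net$drugs)
  if (anyNA(qi) || anyNA(qj)) stop("unknown drug in pairs")
  qt <- pair_view_types(view, qi, qj)

  H <- numeric(nrow(parts))
  est <- array(0, dim = c(nrow(parts), nrow(pairs), K))
  for (p in seq_len(nrow(parts))) {
    g <- parts[p, ]
    H[p] <- -sum(vapply(partition_counts(view, g), log_pair_factor, 0.0,
                        include_prior_constant = include_prior_constant))
    counts <- partition_counts(view, g)
    b <- max(g)
    idx <- function(a, gg) (a - 1L) * (b + 1L) - (a * (a - 1L)) %/% 2L +
      gg - a + 1L
    for (q in seq_len(nrow(pairs))) {
      a <- min(g[qi[q]], g[qj[q]]); gg <- max(g[qi[q]], g[qj[q]])
      nk <- counts[[idx(a, gg)]]
      n <- sum(nk)
      if (qt[q] >= 0L) {
        n <- n - 1L
        nk[qt[q] + 1L] <- nk[qt[q] + 1L] - 1L
      }
      est[p, q, ] <- (nk + 1) / (n + K)
    }
  }
  w <- exp(-(H - min(H)))
  w <- w / sum(w)
  out <- matrix(0, nrow(pairs), K,
                dimnames = list(NULL, net$alphabet$labels))
  for (q in seq_len(nrow(pairs)))
    out[q, ] <- colSums(w * est[, q, ])
  out
}

#' Exact stationary distribution over set partitions
#'
#' Probability `exp(-H)/Z` of every set partition of a tiny network, the
#' distribution the Metropolis chain is designed to sample.
#'
#' @inheritParams exact_link_posterior
#' @return list with `partitions` (matrix from [set_partitions()]), `H`
#'   and `prob`.
#' @export
exact_partition_distribution <- function(net,
                                         mode = c("heldout",
                                                  "fully_observed"),
                                         include_prior_constant = TRUE) {
  mode <- match.arg(mode)
  view <- sbm_view(net, mode)
  parts <- set_partitions(length(net$drugs))
  H <- vapply(seq_len(nrow(parts)), function(p) {
    -sum(vapply(partition_counts(view, parts[p, ]), log_pair_factor, 0.0,
                include_prior_constant = include_prior_constant))
  }, 0.0)
  w <- exp(-(H - min(H)))
  list(partitions = parts, H = H, prob = w / sum(w))
}

#' Exact co-classification probabilities on tiny networks
#'
#' @inheritParams exact_link_posterior
#' @return N x N matrix of exact co-membership probabilities.
#' @export
exact_coclassification <- function(net,
                                   mode = c("heldout", "fully_observed"),
                                   include_prior_constant = TRUE) {
  mode <- match.arg(mode)
  dist <- exact_partition_distribution(net, mode, include_prior_constant)
  N <- length(net$drugs)
  m <- matrix(0, N, N, dimnames = list(net$drugs, net$drugs))
  for (p in seq_len(nrow(dist$partitions))) {
    g <- dist$partitions[p, ]
    m <- m + dist$prob[p] * outer(g, g, "==")
  }
  m
}

# canonical restricted-growth-string key of an assignment (for tabulating
# chain visits against set partitions)
rgs_key <- function(assignment) {
  lab <- integer(0)
  out <- integer(length(assignment))
  for (i in seq_along(assignment)) {
    pos <- match(assignment[i], lab)
    if (is.na(pos)) {
      lab <- c(lab, assignment[i])
      pos <- length(lab)
    }
    out[i] <- pos
  }
  paste(out, collapse = ".")
}
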