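#' Global-rate baseline predictor
#'
#' The simplest predictor: the overall rate of each interaction type among
#' the observed interactions, returned as one probability vector that is
#' the prediction for every query pair.
#'
#' @param net an [interaction_network()] with at least one observation.
#' @return named numeric vector of length K summing to 1.
#' @export
baseline_predict <- function(net) {
  if (nrow(net$obs) == 0L)
    stop("no observed interactions: baseline rate undefined")
  counts <- tabulate(net$obs$type, nbins = net$alphabet$K)
  setNames(counts / sum(counts), net$alphabet$labels)
}

#' Interaction-profile similarity between two drugs
#'
#' `S_ij` is the fraction of interactions with other drugs that are equal
#' for `i` and `j`, over the number of interactions reported for both:
#' partners `z` (distinct from both drugs) whose interactions `x_iz` and
#' `x_jz` are both observed.  `S = 0` when the drugs share reported
#' partners but no equal interaction; when no partner is reported for
#' both, the similarity is undefined (`NA`) and such pairs are excluded
#' from candidate rankings.
#'
#' @param net an [interaction_network()].
#' @param i,j distinct drug names.
#' @return similarity in `[0, 1]`, or `NA` if undefined.
#' @export
interaction_similarity <- function(net, i, j) {
  if (identical(i, j)) stop("similarity of a drug with itself is not defined")
  tm <- type_matrix(net)
  similarity_from_matrix(tm, match(i, net$drugs), match(j, net$drugs))
}

similarity_from_matrix <- function(tm, ii, jj) {
  common <- !is.na(tm[ii, ]) & !is.na(tm[jj, ])
  common[c(ii, jj)] <- FALSE
  n <- sum(common)
  if (n == 0L) return(NA_real_)
  sum(tm[ii, common] == tm[jj, common]) / n
}

#' Pairwise similarity table
#'
#' All pairwise [interaction_similarity()] values.  The diagonal is set to
#' 1 (a drug's profile is perfectly similar to itself), which lets the
#' neighbor predictor use a known interaction `x_kj` of the query drug `j`
#' itself as a candidate.
#'
#' @param net an [interaction_network()].
#' @return symmetric N x N matrix with `NA` for undefined pairs.
#' @export
similarity_table <- function(net) {
  tm <- type_matrix(net)
  N <- length(net$drugs)
  S <- matrix(NA_real_, N, N, dimnames = list(net$drugs, net$drugs))
  for (ii in seq_len(N)) {
    S[ii, ii] <- 1
    for (jj in seq_len(N)[-seq_len(ii)]) {
      s <- similarity_from_matrix(tm, ii, jj)
      S[ii, jj] <- s
      S[jj, ii] <- s
    }
  }
  S
}

#' Neighbor-based prediction
#'
#' Orders all candidate drug pairs `(k, l)` with a known interaction by
#' decreasing product of similarities to the query drugs,
#' `S_ik * S_jl`, and predicts the type of the best candidate's
#' interaction (as an indicator probability vector).  Candidates with an
#' undefined similarity are skipped; `k = j` is allowed (self-similarity
#' 1).  Ties are broken by the larger minimum of the two similarities,
#' then lexicographically.  When no candidate has a positive product the
#' prediction falls back to [baseline_predict()].
#'
#' @param net an [interaction_network()].
#' @param pair length-2 vector of drug names; its own observation, if
#'   present, is masked everywhere (including the similarities) before
#'   predicting.
#' @param S optional precomputed [similarity_table()]; used only when the
#'   query pair is unobserved (masking would not change it), otherwise
#'   the masked table is recomputed.
#' @return named probability vector of length K.
#' @export
neighbor_predict <- function(net, pair, S = NULL) {
  idx <- resolve_pair(net$drugs, pair)
  tm <- type_matrix(net)
  pair_observed <- !is.na(tm[idx[1L], idx[2L]])
  # mask the query pair so predicting an observed pair never sees itself
  tm[idx[1L], idx[2L]] <- NA_integer_
  tm[idx[2L], idx[1L]] <- NA_integer_
  if (is.null(S) || pair_observed) {
    net_masked <- net
    net_masked$obs <- net$obs[!(net$obs$a %in% net$drugs[idx] &
                                  net$obs$b %in% net$drugs[idx]), ,
                              drop = FALSE]
    S <- similarity_table(net_masked)
  }
  N <- length(net$drugs)
  prod <- outer(S[idx[1L], ], S[idx[2L], ])       # prod[k, l] = S_ik * S_jl
  minim <- outer(S[idx[1L], ], S[idx[2L], ], pmin)
  known <- !is.na(tm)                              # known[k, l] = x_kl known
  valid <- known & !is.na(prod) & prod > 0
  if (!any(valid)) return(baseline_predict(net))
  cand <- which(valid, arr.ind = TRUE)
  o <- order(-prod[valid], -minim[valid], cand[, 1L], cand[, 2L])
  best <- cand[o[1L], ]
  out <- numeric(net$alphabet$K)
  out[tm[best[1L], best[2L]]] <- 1
  setNames(out, net$alphabet$labels)
}

# ---------------------------------------------------------------------------
# Prism II: agglomerative monochromatic clustering

#' Prism II configuration
#'
#' @param entropy_weight nonnegative weight of the monochromaticity
#'   entropy change in the group-merge distance.
#' @param cut_threshold tree-cut level: the partition chosen is the one
#'   with fewest groups whose total monochromaticity entropy is at most
#'   `cut_threshold` times the entropy of the single-group partition.
#' @param type_polarity optional integer vector of length K with values
#'   -1 (synergistic-like), 0 (neutral, excluded from the entropy) and
#'   +1 (antagonistic-like).  Defaults: binary none/interaction alphabets
#'   map to `c(-1, 1)`; ordered K = 3 to `c(-1, 0, 1)`; ordered K = 4 to
#'   `c(-1, 0, 1, 1)` (suppressing counts as antagonistic-like).
#' @return a `prism_config` object.
#' @export
prism_config <- function(entropy_weight = 1, cut_threshold = 0.1,
                         type_polarity = NULL) {
  stopifnot(entropy_weight >= 0, cut_threshold >= 0, cut_threshold <= 1)
  structure(list(entropy_weight = entropy_weight,
                 cut_threshold = cut_threshold,
                 type_polarity = type_polarity),
            class = "prism_config")
}

resolve_polarity <- function(alphabet, config) {
  pol <- config$type_polarity
  if (!is.null(pol)) {
    stopifnot(length(pol) == alphabet$K, all(pol %in% c(-1, 0, 1)))
    return(pol)
  }
  if (alphabet$K == 2L) return(c(-1, 1))
  if (alphabet$ordered && alphabet$K == 3L) return(c(-1, 0, 1))
  if (alphabet$ordered && alphabet$K == 4L) return(c(-1, 0, 1, 1))
  stop("no default type polarity for this alphabet; set type_polarity")
}

#' Normalized drug-drug distance
#'
#' Profile dissimilarity used by Prism II: the complement of
#' [interaction_similarity()], with undefined similarities treated as
#' maximally distant (1).
#'
#' @inheritParams interaction_similarity
#' @return distance in `[0, 1]`.
#' @export
prism_drug_distance <- function(net, i, j) {
  s <- interaction_similarity(net, i, j)
  if (is.na(s)) 1 else 1 - s
}

#' Monochromaticity entropy of a count vector
#'
#' For `v = (v_minus, v_plus)` synergistic-like / antagonistic-like
#' interaction counts between two groups,
#' `S(v) = (v_minus + v_plus) * (-f_minus*log(f_minus) -
#' f_plus*log(f_plus))` with `0 log 0 = 0`; zero for perfectly
#' monochromatic (or empty) group pairs.
#'
#' @param v length-2 nonnegative count vector.
#' @return entropy in nats.
#' @export
monochromaticity_entropy <- function(v) {
  if (length(v) != 2L || any(v < 0)) stop("v must be 2 nonnegative counts")
  n <- sum(v)
  if (n == 0) return(0)
  f <- v / n
  f <- f[f > 0]
  n * sum(-f * log(f))
}

# per-group-pair (minus, plus) count array for an assignment
polarity_counts <- function(net, groups, pol) {
  b <- max(groups)
  vminus <- matrix(0, b, b)
  vplus <- matrix(0, b, b)
  ia <- match(net$obs$a, net$drugs); ib <- match(net$obs$b, net$drugs)
  ga <- groups[ia]; gb <- groups[ib]
  lo <- pmin(ga, gb); hi <- pmax(ga, gb)
  p <- pol[net$obs$type]
  for (e in seq_along(lo)) {
    if (p[e] < 0) vminus[lo[e], hi[e]] <- vminus[lo[e], hi[e]] + 1
    if (p[e] > 0) vplus[lo[e], hi[e]] <- vplus[lo[e], hi[e]] + 1
  }
  list(vminus = vminus, vplus = vplus)
}

total_entropy <- function(net, groups, pol) {
  pc <- polarity_counts(net, groups, pol)
  b <- max(groups)
  tot <- 0
  for (a in seq_len(b)) for (g in a:b)
    tot <- tot + monochromaticity_entropy(c(pc$vminus[a, g], pc$vplus[a, g]))
  tot
}

#' Build the Prism II tree
#'
#' Agglomerative clustering of drugs: starting from singletons, the two
#' groups with the smallest distance are merged until one group remains.
#' The group distance combines the mean normalized drug-drug distance
#' across the two groups with the change in total monochromaticity
#' entropy the merge would cause, weighted by `entropy_weight`.  Ties are
#' broken by the lexicographically smallest group-id pair, making the
#' tree deterministic.
#'
#' @param net an [interaction_network()] with at least 2 drugs.
#' @param config a [prism_config()].
#' @return An object of class `prism_tree`: data frame of `N - 1` merges
#'   (`g1`, `g2`, `new_id`, `distance`), singleton ids `1..N` in drug
#'   order, merged ids `N+1..2N-1`.
#' @export
prism_build_tree <- function(net, config = prism_config()) {
  N <- length(net$drugs)
  stopifnot(N >= 2L)
  pol <- resolve_polarity(net$alphabet, config)
  tm <- type_matrix(net)
  D <- matrix(1, N, N)
  for (ii in seq_len(N - 1L)) for (jj in (ii + 1L):N) {
    s <- similarity_from_matrix(tm, ii, jj)
    D[ii, jj] <- D[jj, ii] <- if (is.na(s)) 1 else 1 - s
  }

  members <- as.list(seq_len(N))     # active group -> drug indices
  ids <- seq_len(N)                  # active group -> tree id
  groups_of <- function() {          # current assignment vector
    g <- integer(N)
    for (a in seq_along(members)) g[members[[a]]] <- a
    g
  }
  merges <- data.frame(g1 = integer(N - 1L), g2 = integer(N - 1L),
                       new_id = integer(N - 1L), distance = numeric(N - 1L))
  for (step in seq_len(N - 1L)) {
    g <- groups_of()
    S_now <- total_entropy(net, g, pol)
    na <- length(members)
    best <- NULL
    for (a in seq_len(na - 1L)) for (bb in (a + 1L):na) {
      dmean <- mean(D[members[[a]], members[[bb]]])
      gm <- g
      gm[gm == bb] <- a
      gm <- as.integer(factor(gm))
      dS <- total_entropy(net, gm, pol) - S_now
      dist <- dmean + config$entropy_weight * dS
      key <- c(dist, ids[a], ids[bb])
      if (is.null(best) || dist < best$dist - 1e-12 ||
          (abs(dist - best$dist) <= 1e-12 &&
           (ids[a] < best$ida || (ids[a] == best$ida && ids[bb] < best$idb)))) {
        best <- list(a = a, b = bb, dist = dist, ida = ids[a], idb = ids[bb])
      }
    }
    merges$g1[step] <- ids[best$a]
    merges$g2[step] <- ids[best$b]
    merges$new_id[step] <- N + step
    merges$distance[step] <- best$dist
    members[[best$a]] <- c(members[[best$a]], members[[best$b]])
    members[[best$b]] <- NULL
    ids[best$a] <- N + step
    ids <- ids[-best$b]
  }
  structure(list(merges = merges, drugs = net$drugs), class = "prism_tree")
}

#' @export
print.prism_tree <- function(x, ...) {
  cat("Prism II tree:", length(x$drugs), "drugs,", nrow(x$merges),
      "merges\n")
  invisible(x)
}

#' Write a Prism II tree as a text merge list
#' @param tree a `prism_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prism_tree <- function(tree, path) {
  write.table(tree$merges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# the N nested partitions of the tree, from singletons to one group
nested_partitions <- function(tree) {
  N <- length(tree$drugs)
  id_members <- as.list(seq_len(N))
  active <- seq_len(N)
  parts <- vector("list", N)
  snap <- function(active) {
    g <- integer(N)
    for (a in seq_along(active)) g[id_members[[active[a]]]] <- a
    g
  }
  parts[[1L]] <- snap(active)
  for (step in seq_len(N - 1L)) {
    m <- tree$merges[step, ]
    id_members[[m$new_id]] <- c(id_members[[m$g1]], id_members[[m$g2]])
    active <- c(setdiff(active, c(m$g1, m$g2)), m$new_id)
    parts[[step + 1L]] <- snap(active)
  }
  parts
}

#' Cut the Prism II tree into a single partition
#'
#' Scans the N nested partitions of the tree and returns the one with the
#' fewest groups among those whose total monochromaticity entropy is at
#' most `cut_threshold` times the entropy of the single-group partition.
#' If no partition satisfies the threshold the all-singletons partition
#' is returned with a warning.
#'
#' @param tree a `prism_tree` from [prism_build_tree()].
#' @param net the network the tree was built from.
#' @param config a [prism_config()].
#' @return integer group-assignment vector named by drugs.
#' @export
prism_cut_tree <- function(tree, net, config = prism_config()) {
  pol <- resolve_polarity(net$alphabet, config)
  parts <- nested_partitions(tree)
  ent <- vapply(parts, function(g) total_entropy(net, g, pol), 0.0)
  s1 <- ent[[length(ent)]]            # single-group partition
  ok <- ent <= config$cut_threshold * s1 + 1e-12
  if (!any(ok)) {
    warning("no partition satisfies the entropy threshold; ",
            "returning all singletons")
    g <- parts[[1L]]
  } else {
    ngroups <- vapply(parts, max, 0L)
    cand <- which(ok)
    g <- parts[[cand[which.min(ngroups[cand])]]]
  }
  setNames(g, net$drugs)
}

#' Prism II type prediction for a pair
#'
#' Given a fixed partition (from [prism_cut_tree()]), predicts the
#' interaction-type probabilities of a pair from the type counts between
#' its two groups with Laplace smoothing: `(n^k + 1) / (n + K)`.  This is
#' the same estimator the block-model average applies per sampled
#' partition, evaluated at a single partition.
#'
#' @param net an [interaction_network()].
#' @param groups integer assignment vector (one entry per drug).
#' @param pair length-2 vector of drug names.
#' @param exclude_self if TRUE, the pair's own observation (if stored) is
#'   removed from the counts first.
#' @return named probability vector of length K.
#' @export
prism_predict <- function(net, groups, pair, exclude_self = FALSE) {
  idx <- resolve_pair(net$drugs, pair)
  K <- net$alphabet$K
  ia <- match(net$obs$a, net$drugs); ib <- match(net$obs$b, net$drugs)
  ga <- groups[ia]; gb <- groups[ib]
  qa <- min(groups[idx]); qb <- max(groups[idx])
  sel <- pmin(ga, gb) == qa & pmax(ga, gb) == qb
  nk <- tabulate(net$obs$type[sel], nbins = K)
  if (exclude_self) {
    own <- which((ia == idx[1L] & ib == idx[2L]) |
                   (ia == idx[2L] & ib == idx[1L]))
    if (length(own)) nk[net$obs$type[own]] <- nk[net$obs$type[own]] - 1L
  }
  setNames((nk + 1) / (sum(nk) + K), net$alphabet$labels)
}
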