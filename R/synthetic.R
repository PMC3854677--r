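#' Planted block-structure network model
#'
#' Generative counterpart of the stochastic block model used for
#' inference: drugs are partitioned into groups and each drug pair draws
#' its interaction type from the type-probability vector of its group
#' pair.  Networks generated this way have a known ground truth, so every
#' predictor and evaluation protocol can be verified without external
#' data.
#'
#' @param group_sizes integer vector of group sizes; their sum is the
#'   number of drugs.
#' @param alphabet a [type_alphabet()].
#' @param theta type-distribution array: either a `G x G x K` array
#'   (symmetric in its first two margins) or a function
#'   `(alpha, beta) -> length-K` probability vector.
#' @param observed_fraction fraction of pairs marked observed in the
#'   returned observed view.
#' @return a `planted_model` object.
#' @export
planted_model <- function(group_sizes, alphabet, theta,
                          observed_fraction = 1) {
  stopifnot(all(group_sizes >= 1L), observed_fraction > 0,
            observed_fraction <= 1)
  G <- length(group_sizes)
  K <- alphabet$K
  if (is.function(theta)) {
    th <- array(0, dim = c(G, G, K))
    for (a in seq_len(G)) for (b in seq_len(G)) th[a, b, ] <- theta(a, b)
    theta <- th
  }
  stopifnot(identical(dim(theta), c(G, G, as.integer(K))) ||
              identical(dim(theta), c(G, G, K)))
  for (a in seq_len(G)) for (b in seq_len(G)) {
    if (abs(sum(theta[a, b, ]) - 1) > 1e-9)
      stop("theta rows must sum to 1")
    if (any(theta[a, b, ] < 0)) stop("theta entries must be nonnegative")
    if (max(abs(theta[a, b, ] - theta[b, a, ])) > 1e-12)
      stop("theta must be symmetric in its group margins")
  }
  structure(list(group_sizes = as.integer(group_sizes),
                 alphabet = alphabet, theta = theta,
                 observed_fraction = observed_fraction,
                 n_drugs = sum(group_sizes)),
            class = "planted_model")
}

#' Generate a network from a planted model
#'
#' Every drug pair draws its type from the model; a fraction
#' `observed_fraction` of pairs (uniformly random) forms the observed
#' view.  For the binary none/interaction alphabet only positive pairs
#' are stored, matching how interaction databases list links.
#'
#' @param model a [planted_model()].
#' @param seed integer seed.
#' @param drug_names optional drug identifiers (default `d001, d002, ...`
#'   in group order).
#' @return list with `net` (full truth), `observed` (observed view),
#'   `groups` (named ground-truth assignment) and `model`.
#' @export
generate_planted_network <- function(model, seed = 1L, drug_names = NULL) {
  stopifnot(inherits(model, "planted_model"))
  set.seed(seed)
  N <- model$n_drugs
  K <- model$alphabet$K
  groups <- rep(seq_along(model$group_sizes), model$group_sizes)
  if (is.null(drug_names))
    drug_names <- sprintf("d%03d", seq_len(N))
  stopifnot(length(drug_names) == N, !anyDuplicated(drug_names))
  ij <- combn(N, 2L)
  ty <- integer(ncol(ij))
  for (p in seq_len(ncol(ij))) {
    th <- model$theta[groups[ij[1L, p]], groups[ij[2L, p]], ]
    ty[p] <- sample.int(K, 1L, prob = th)
  }
  binary <- is_binary_alphabet(model$alphabet)
  keep_row <- if (binary) ty == 2L else rep(TRUE, length(ty))
  edges <- data.frame(drug_a = drug_names[ij[1L, keep_row]],
                      drug_b = drug_names[ij[2L, keep_row]],
                      type = model$alphabet$labels[ty[keep_row]])
  net <- interaction_network(edges, model$alphabet, drugs = drug_names)
  observed <- net
  if (model$observed_fraction < 1) {
    obs_pairs <- sort(sample.int(ncol(ij),
                                 ceiling(model$observed_fraction * ncol(ij))))
    sel <- logical(ncol(ij))
    sel[obs_pairs] <- TRUE
    keep_obs <- sel & keep_row
    edges_o <- data.frame(drug_a = drug_names[ij[1L, keep_obs]],
                          drug_b = drug_names[ij[2L, keep_obs]],
                          type = model$alphabet$labels[ty[keep_obs]])
    observed <- interaction_network(edges_o, model$alphabet,
                                    drugs = drug_names)
  }
  list(net = net, observed = observed,
       groups = setNames(groups, drug_names), model = model)
}

#' Perturb a binary snapshot
#'
#' Removes `n_spurious` random edges and adds `n_novel` random non-edges,
#' returning the perturbed network together with the truth diff.  Used to
#' build snapshot pairs with known novel/spurious sets: perturbing the
#' TRUE network yields an earlier, partially wrong snapshot whose diff
#' against the truth has the removed (structure-consistent) edges as
#' novel and the added random edges as spurious.
#'
#' @param net a binary [interaction_network()].
#' @param n_novel edges to add.
#' @param n_spurious edges to remove.
#' @param seed integer seed.
#' @return list with `net` (the perturbed network) and `diff`
#'   ([diff_snapshots()] of perturbed vs original).
#' @export
perturb_snapshot <- function(net, n_novel, n_spurious, seed = 1L) {
  if (!is_binary_alphabet(net$alphabet))
    stop("perturb_snapshot requires a binary network")
  set.seed(seed)
  M <- nrow(net$obs)
  if (n_spurious > M) stop("not enough edges to remove")
  N <- length(net$drugs)
  ij <- combn(N, 2L)
  key_all <- paste(ij[1L, ], ij[2L, ])
  ia <- match(net$obs$a, net$drugs); ib <- match(net$obs$b, net$drugs)
  key_edges <- paste(pmin(ia, ib), pmax(ia, ib))
  nonedges <- which(!(key_all %in% key_edges))
  if (n_novel > length(nonedges)) stop("not enough non-edges to add")
  drop <- if (n_spurious > 0L) sample.int(M, n_spurious) else integer(0)
  add <- if (n_novel > 0L) sample(nonedges, n_novel) else integer(0)
  obs <- net$obs[setdiff(seq_len(M), drop), , drop = FALSE]
  if (length(add)) {
    obs <- rbind(obs, data.frame(a = net$drugs[ij[1L, add]],
                                 b = net$drugs[ij[2L, add]],
                                 type = 2L))
  }
  out <- interaction_network(
    data.frame(drug_a = obs$a, drug_b = obs$b,
               type = net$alphabet$labels[obs$type]),
    net$alphabet, drugs = net$drugs)
  list(net = out, diff = diff_snapshots(net, out))
}

#' Exhaustive pairwise-screen fixtures
#'
#' Synthetic stand-ins for the two exhaustive pairwise interaction
#' experiments used for validation: `"cokol"` style (13 drugs, all 78
#' pairs typed on the ordered K = 3 alphabet synergistic < additive <
#' antagonistic, as in an anti-fungal screen) and `"yeh"` style (21
#' drugs, all 210 pairs typed on the ordered K = 4 alphabet with
#' suppressing added, as in an antibiotic screen).  Both are generated
#' from a planted model with three (resp. four) mechanism-of-action
#' groups and a dominant type per group pair (probability 0.8), chosen so
#' group structure is recoverable at half-observed networks; they emulate
#' the designs' size and alphabet, not the real measured matrices.
#'
#' @param style `"cokol"` or `"yeh"`.
#' @param seed integer seed.
#' @return an [interaction_network()] with the ground-truth groups as
#'   attribute `groups`.
#' @export
make_exhaustive_fixture <- function(style = c("cokol", "yeh"), seed = 1L) {
  style <- match.arg(style)
  if (style == "cokol") {
    alphabet <- type_alphabet(c("synergistic", "additive", "antagonistic"),
                              ordered = TRUE)
    sizes <- c(5L, 4L, 4L)
  } else {
    alphabet <- type_alphabet(c("synergistic", "additive", "antagonistic",
                                "suppressing"), ordered = TRUE)
    sizes <- c(6L, 5L, 5L, 5L)
  }
  K <- alphabet$K
  dominant <- function(a, b) (a + b - 2L) %% K + 1L
  theta <- function(a, b) {
    th <- rep(0.2 / (K - 1), K)
    th[dominant(a, b)] <- 0.8
    th
  }
  model <- planted_model(sizes, alphabet, theta, observed_fraction = 1)
  gen <- generate_planted_network(model, seed = seed)
  structure(gen$net, groups = gen$groups)
}
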