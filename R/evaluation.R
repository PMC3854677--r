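#' Hard classification from a probability vector
#'
#' Argmax over types; ties are broken by the lowest type index, so the
#' call is deterministic.
#'
#' @param probs normalized probability vector.
#' @return 1-based type index.
#' @export
classify_from_probs <- function(probs) {
  which.max(probs)
}

#' Within-one-level correctness
#'
#' On an ordered type alphabet (e.g. synergistic < additive <
#' antagonistic < suppressing), a prediction counts as correct if it is
#' at most one level away from the observed type: synergistic predicted
#' as additive is correct, synergistic predicted as antagonistic or
#' suppressing is not.
#'
#' @param predicted,truth 1-based type indices.
#' @param alphabet an ordered [type_alphabet()].
#' @return logical.
#' @export
within_one_correct <- function(predicted, truth, alphabet) {
  if (!alphabet$ordered)
    stop("within-one-level classification requires an ordered alphabet")
  abs(predicted - truth) <= 1L
}

#' Repeated random sub-sampling validation
#'
#' Simulates partial knowledge of an exhaustively measured network: per
#' repetition, a uniformly random subset of `ceiling(f * M)` of the `M`
#' observed pairs is kept as the training network, every predictor is fit
#' on it and queried on the complement, and exact and (for ordered
#' alphabets) within-one-level accuracies are recorded.
#'
#' @param net a fully (or extensively) observed [interaction_network()].
#' @param predictors a single `ddi_predictor` or list of them.
#' @param f fraction of observed pairs kept, 0 < f < 1.
#' @param n_reps repetitions.
#' @param seed integer seed; repetition r uses `seed + r` so runs are
#'   reproducible and extensible.
#' @return An object of class `validation_result`: data frame with one
#'   row per repetition x predictor (`rep`, `predictor`, `exact`,
#'   `within_one`, `n_queries`) plus attribute `f`; summarize with
#'   [summarize_validation()].
#' @export
subsample_validate <- function(net, predictors, f, n_reps = 10L, seed = 1L) {
  stopifnot(f > 0, f < 1)
  if (inherits(predictors, "ddi_predictor")) predictors <- list(predictors)
  M <- nrow(net$obs)
  keep_n <- ceiling(f * M)
  if (keep_n < 1L) stop("f * M < 1: nothing to train on")
  if (keep_n >= M) stop("f too large: nothing left to predict")
  ordered <- net$alphabet$ordered
  rows <- list()
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    keep <- sample.int(M, keep_n)
    train <- net
    train$obs <- net$obs[keep, , drop = FALSE]
    test <- net$obs[-keep, , drop = FALSE]
    pairs <- cbind(test$a, test$b)
    for (pred in predictors) {
      p <- predict_pairs(pred, train, pairs)
      cls <- apply(p, 1L, classify_from_probs)
      exact <- mean(cls == test$type)
      w1 <- if (ordered) mean(abs(cls - test$type) <= 1L) else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(rep = r, predictor = pred$name, exact = exact,
                   within_one = w1, n_queries = nrow(test))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "f") <- f
  class(out) <- c("validation_result", class(out))
  out
}

#' Summarize a validation result
#'
#' Mean accuracies and standard errors of the mean over repetitions, per
#' predictor.
#'
#' @param result a `validation_result` from [subsample_validate()].
#' @return data frame with columns `predictor`, `exact`, `exact_se`,
#'   `within_one`, `within_one_se`.
#' @export
summarize_validation <- function(result) {
  sem <- function(x) if (length(x) > 1L) sd(x) / sqrt(length(x)) else 0
  agg <- function(col, fn) {
    v <- tapply(result[[col]], result$predictor, fn)
    v[unique(result$predictor)]
  }
  data.frame(predictor = unique(result$predictor),
             exact = as.numeric(agg("exact", mean)),
             exact_se = as.numeric(agg("exact", sem)),
             within_one = as.numeric(agg("within_one", mean)),
             within_one_se = as.numeric(agg("within_one", sem)),
             row.names = NULL)
}

#' Relative improvement over a benchmark, measured against the baseline
#'
#' `(F_sbm - F_x) / (F_x - F_baseline)`: how much of the benchmark's
#' advantage over the baseline the block model adds on top.  Undefined
#' when the benchmark does not differ from the baseline.
#'
#' @param f_sbm,f_x,f_baseline accuracies of the block model, the
#'   benchmark, and the baseline.
#' @return the relative improvement (negative denominators, i.e.
#'   benchmarks below baseline, flip the sign accordingly); `NA` with a
#'   warning when `f_x == f_baseline`.
#' @export
relative_improvement <- function(f_sbm, f_x, f_baseline) {
  if (isTRUE(all.equal(f_x, f_baseline))) {
    warning("benchmark equals baseline: relative improvement undefined")
    return(NA_real_)
  }
  (f_sbm - f_x) / (f_x - f_baseline)
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney estimate: the probability that a randomly chosen positive
#' scores higher than a randomly chosen negative, ties counted one half.
#'
#' @param scores_pos,scores_neg non-empty numeric score vectors.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg))
    stop("both score lists must be non-empty")
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  np <- length(scores_pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(scores_neg))
}

#' Sensitivity-specificity curve
#'
#' Sweeps a threshold over all scores (predicted positive = score at or
#' above the threshold).  Sensitivity is the fraction of positives
#' recovered; specificity the fraction of negatives excluded.  The
#' trapezoid area under sensitivity vs (1 - specificity) equals
#' [auroc()].
#'
#' @inheritParams auroc
#' @return An object of class `roc_result`: data frame (`threshold`,
#'   `sensitivity`, `specificity`) with the AUROC as attribute `auroc`.
#' @export
sensitivity_specificity_curve <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg))
    stop("both score lists must be non-empty")
  th <- c(Inf, sort(unique(c(scores_pos, scores_neg)), decreasing = TRUE))
  sens <- vapply(th, function(t) mean(scores_pos >= t), 0.0)
  spec <- vapply(th, function(t) mean(scores_neg < t), 0.0)
  out <- data.frame(threshold = th, sensitivity = sens, specificity = spec)
  attr(out, "auroc") <- auroc(scores_pos, scores_neg)
  class(out) <- c("roc_result", class(out))
  out
}

#' Trapezoid area under an ROC curve
#' @param roc a `roc_result`.
#' @return area under sensitivity vs (1 - specificity).
#' @export
roc_trapezoid_area <- function(roc) {
  x <- 1 - roc$specificity
  y <- roc$sensitivity
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Specificity at a sensitivity floor (and vice versa)
#'
#' @param roc a `roc_result`.
#' @param sensitivity,specificity the required level.
#' @return the best specificity among thresholds achieving at least the
#'   given sensitivity (resp. best sensitivity at the given specificity).
#' @export
specificity_at_sensitivity <- function(roc, sensitivity) {
  ok <- roc$sensitivity >= sensitivity
  if (!any(ok)) return(0)
  max(roc$specificity[ok])
}

#' @rdname specificity_at_sensitivity
#' @export
sensitivity_at_specificity <- function(roc, specificity) {
  ok <- roc$specificity >= specificity
  if (!any(ok)) return(0)
  max(roc$sensitivity[ok])
}

#' Novel- and spurious-interaction detection between snapshots
#'
#' Scores every pair of the earlier snapshot with the predictor in
#' fully-observed binary mode and evaluates two retrieval problems
#' against the later snapshot: novel interactions (positives = pairs
#' added later, negatives = pairs never added) ranked by the
#' p(interaction) score, and spurious interactions (positives = pairs
#' removed later, negatives = persistent pairs) ranked by the negated
#' score, so that in both problems a higher score means "more likely a
#' detection" and one AUROC convention applies.
#'
#' @param net1,net2 earlier and later binary snapshots over shared drugs.
#' @param predictor a `ddi_predictor`; for the block model use
#'   `sbm_predictor(config, mode = "fully_observed")`.
#' @return list with `novel` and `spurious` (`roc_result` objects), the
#'   `diff` ([diff_snapshots()]) and the score table.
#' @export
evaluate_snapshots <- function(net1, net2, predictor) {
  d <- diff_snapshots(net1, net2)
  if (nrow(d$novel) == 0L && nrow(d$spurious) == 0L)
    stop("snapshots are identical: no positives to evaluate")
  net1s <- net1
  keep <- net1$obs$a %in% d$drugs & net1$obs$b %in% d$drugs
  net1s$obs <- net1$obs[keep, , drop = FALSE]
  net1s$drugs <- d$drugs
  pairs <- all_pairs(net1s)
  p <- predict_pairs(predictor, net1s, pairs)
  int_col <- match("interaction", net1$alphabet$labels)
  score <- p[, int_col]
  key <- paste(pairs[, 1L], pairs[, 2L])
  lookup <- function(set) {
    if (!nrow(set)) return(numeric(0))
    a <- pmin(set[, 1L], set[, 2L]); b <- pmax(set[, 1L], set[, 2L])
    score[match(paste(a, b), key)]
  }
  novel <- if (nrow(d$novel))
    sensitivity_specificity_curve(lookup(d$novel), lookup(d$never_added))
  else NULL
  spurious <- if (nrow(d$spurious))
    sensitivity_specificity_curve(-lookup(d$spurious), -lookup(d$persistent))
  else NULL
  list(novel = novel, spurious = spurious, diff = d,
       scores = data.frame(drug_a = pairs[, 1L], drug_b = pairs[, 2L],
                           score = score))
}

#' Iterative discovery of a new drug's interactions
#'
#' Emulates the discovery setting: a target drug whose only listed
#' interaction is one seed link, in an otherwise fully listed database.
#' At each iteration the block model scores all unqueried candidate pairs
#' involving the target (fully-observed binary semantics, with the
#' candidate pair's own non-edge left out of the counts), the
#' highest-scoring candidate is "tested" against the truth, confirmed
#' interactions are added to the database, and the process repeats.
#'
#' @param net the true binary [interaction_network()] (all non-target
#'   information is taken as known).
#' @param target drug whose interactions are being discovered; must have
#'   at least one true interaction.
#' @param seed_partner a drug that truly interacts with `target`.
#' @param n_iters number of experiments (queries).
#' @param config a [sampler_config()] for the block-model scoring.
#' @return An object of class `discovery_trace`: data frame (`iteration`,
#'   `candidate`, `hit`, `cumulative_hits`) with attributes `degree`
#'   (target's remaining true interactions after the seed), `upper` and
#'   `lower` feasible-region bounds (oracle curve and expected curve of
#'   uniformly random querying).
#' @export
discovery_simulation <- function(net, target, seed_partner, n_iters,
                                 config = sampler_config()) {
  if (!is_binary_alphabet(net$alphabet))
    stop("discovery simulation requires a binary network")
  stopifnot(target %in% net$drugs, seed_partner %in% net$drugs)
  tm <- type_matrix(net)
  it <- match(target, net$drugs)
  true_partners <- net$drugs[which(!is.na(tm[it, ]) & tm[it, ] == 2L)]
  if (!length(true_partners))
    stop("target has no true interactions")
  if (!(seed_partner %in% true_partners))
    stop("seed_partner does not truly interact with the target")

  # observed database view (fully-observed binary semantics): all
  # non-target links are listed, the target contributes only the seed
  # interaction plus whatever the queries have confirmed; unqueried and
  # confirmed-negative target pairs alike are non-edges of the database
  obs <- net$obs[net$obs$a != target & net$obs$b != target, , drop = FALSE]
  obs <- rbind(obs, data.frame(a = min(target, seed_partner),
                               b = max(target, seed_partner),
                               type = 2L))
  candidates <- setdiff(net$drugs, c(target, seed_partner))
  d_rem <- length(setdiff(true_partners, seed_partner))
  rows <- list()
  hits <- 0L
  for (iter in seq_len(n_iters)) {
    if (!length(candidates)) break
    work <- net
    work$obs <- obs
    cfg <- config
    cfg$seed <- config$seed + iter
    samples <- run_sampler(work, cfg, mode = "fully_observed")
    qi <- rep(match(target, net$drugs), length(candidates))
    qj <- match(candidates, net$drugs)
    qt <- pair_view_types(samples$view, qi, qj)
    p <- sbm_posterior_cpp(samples$assign, samples$view$edges,
                           samples$view$N, samples$view$K,
                           qi - 1L, qj - 1L, qt)
    score <- p[, 2L]
    best <- which.max(score)
    cand <- candidates[best]
    hit <- cand %in% true_partners
    hits <- hits + as.integer(hit)
    rows[[iter]] <- data.frame(iteration = iter, candidate = cand,
                               hit = hit, cumulative_hits = hits)
    if (hit) {
      obs <- rbind(obs, data.frame(a = min(target, cand),
                                   b = max(target, cand), type = 2L))
    }
    candidates <- candidates[-best]
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(iteration = integer(), candidate = character(),
               hit = logical(), cumulative_hits = integer())
  n_pool <- length(net$drugs) - 2L   # candidates excluding target and seed
  q <- seq_len(max(n_iters, 1L))
  attr(out, "degree") <- d_rem
  attr(out, "upper") <- pmin(q, d_rem)
  attr(out, "lower") <- q * d_rem / n_pool
  class(out) <- c("discovery_trace", class(out))
  out
}
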