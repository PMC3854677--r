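#' Typed undirected interaction networks
#'
#' An interaction network holds a set of drugs, a type alphabet, and a set
#' of observed typed pairs (the observed network that predictions condition
#' on).  Pairs are unordered, self-pairs are forbidden, and each observed
#' pair carries exactly one type.
#'
#' @param edges data frame (or NULL for no observations) with columns
#'   `drug_a`, `drug_b`, `type`; `type` entries must be labels of
#'   `alphabet`.  Duplicate rows with identical type collapse silently;
#'   duplicate pairs with conflicting types are an error.
#' @param alphabet a [type_alphabet()].
#' @param drugs optional character vector of node identifiers; defaults to
#'   the drugs appearing in `edges`.  Identifiers are opaque strings
#'   (whitespace-trimmed, no other normalization).
#' @return An object of class `interaction_network` with fields `drugs`,
#'   `alphabet` and `obs` (data frame `a`, `b`, `type` with `type` a
#'   1-based index into `alphabet$labels` and `a` before `b` in `drugs`
#'   order).
#' @examples
#' ab <- type_alphabet(c("syn", "add", "ant"), ordered = TRUE)
#' net <- interaction_network(
#'   data.frame(drug_a = c("A", "B"), drug_b = c("B", "C"),
#'              type = c("syn", "ant")), ab)
#' net
#' @export
interaction_network <- function(edges, alphabet, drugs = NULL) {
  stopifnot(inherits(alphabet, "type_alphabet"))
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(drug_a = character(), drug_b = character(),
                        type = character())
  }
  edges <- as.data.frame(edges)
  stopifnot(all(c("drug_a", "drug_b", "type") %in% names(edges)))
  a <- trimws(as.character(edges$drug_a))
  b <- trimws(as.character(edges$drug_b))
  if (any(a == b))
    stop("self-loop row(s): a drug cannot interact with itself (",
         paste(unique(a[a == b]), collapse = ", "), ")")
  ty <- type_index(trimws(as.character(edges$type)), alphabet)

  if (is.null(drugs)) {
    drugs <- sort(unique(c(a, b)))
  } else {
    drugs <- trimws(as.character(drugs))
    if (anyDuplicated(drugs)) stop("duplicate drug identifiers")
    missing_d <- setdiff(unique(c(a, b)), drugs)
    if (length(missing_d))
      stop("edge endpoint(s) not in drug set: ",
           paste(missing_d, collapse = ", "))
  }

  ia <- match(a, drugs); ib <- match(b, drugs)
  swap <- ia > ib
  tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp
  key <- paste(ia, ib)
  # conflicting duplicates are an error, not last-wins
  agg <- tapply(ty, key, function(v) length(unique(v)))
  if (any(agg > 1L)) {
    bad <- names(agg)[agg > 1L][1L]
    ij <- as.integer(strsplit(bad, " ")[[1L]])
    stop(sprintf("conflicting types for pair (%s, %s)",
                 drugs[ij[1L]], drugs[ij[2L]]))
  }
  keep <- !duplicated(key)
  obs <- data.frame(a = drugs[ia[keep]], b = drugs[ib[keep]],
                    type = ty[keep], stringsAsFactors = FALSE)
  obs <- obs[order(match(obs$a, drugs), match(obs$b, drugs)), , drop = FALSE]
  rownames(obs) <- NULL
  structure(list(drugs = drugs, alphabet = alphabet, obs = obs),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network: ", length(x$drugs), " drugs, ",
      nrow(x$obs), " observed pairs\n", sep = "")
  print(x$alphabet)
  invisible(x)
}

#' @export
`==.interaction_network` <- function(e1, e2) {
  identical(e1$drugs, e2$drugs) &&
    identical(e1$alphabet$labels, e2$alphabet$labels) &&
    identical(e1$alphabet$ordered, e2$alphabet$ordered) &&
    identical(e1$obs, e2$obs)
}

#' Number of drugs / observed pairs
#' @param net an [interaction_network()].
#' @return integer count.
#' @export
n_drugs <- function(net) length(net$drugs)

#' @rdname n_drugs
#' @export
n_observations <- function(net) nrow(net$obs)

# 0-based integer edge matrix (i, j, type) for the C++ core
edge_matrix <- function(net) {
  cbind(match(net$obs$a, net$drugs) - 1L,
        match(net$obs$b, net$drugs) - 1L,
        net$obs$type - 1L)
}

#' Observed types as a symmetric matrix
#'
#' @param net an [interaction_network()].
#' @return N x N integer matrix of 1-based type indices, `NA` where the
#'   pair is unobserved, `NA` on the diagonal.
#' @export
type_matrix <- function(net) {
  n <- length(net$drugs)
  m <- matrix(NA_integer_, n, n, dimnames = list(net$drugs, net$drugs))
  ia <- match(net$obs$a, net$drugs); ib <- match(net$obs$b, net$drugs)
  m[cbind(ia, ib)] <- net$obs$type
  m[cbind(ib, ia)] <- net$obs$type
  m
}

#' All unordered drug pairs of a network
#' @param net an [interaction_network()].
#' @return two-column character matrix of all `choose(N, 2)` pairs.
#' @export
all_pairs <- function(net) {
  t(combn(net$drugs, 2L))
}

#' Read an interaction network from an edge-list file
#'
#' The file format is UTF-8 text with one `drug_a<TAB>drug_b<TAB>type` row
#' per observed pair (comma-separated also accepted); lines starting with
#' `#` are comments.  A header comment of the form
#' `# alphabet: syn,add,ant` (optionally with `# ordered: true`) declares
#' the alphabet and is used when `alphabet` is NULL.
#'
#' @param path file path.
#' @param alphabet a [type_alphabet()], or NULL to take it from the file
#'   header.
#' @return An [interaction_network()].
#' @export
read_network <- function(path, alphabet = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  header_ab <- grep("^#\\s*alphabet\\s*:", lines, value = TRUE)
  if (is.null(alphabet)) {
    if (!length(header_ab))
      stop("no alphabet given and no '# alphabet:' header in ", path)
    labels <- trimws(strsplit(sub("^#\\s*alphabet\\s*:", "", header_ab[1L]),
                              ",")[[1L]])
    ord <- any(grepl("^#\\s*ordered\\s*:\\s*true", lines, ignore.case = TRUE))
    alphabet <- type_alphabet(labels, ordered = ord)
  }
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(interaction_network(NULL, alphabet))
  }
  rows <- lines[idx]
  sep <- if (any(grepl("\t", rows))) "\t" else ","
  parts <- strsplit(rows, sep, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L))
    stop(sprintf("parse error at line %d of %s: expected 3 fields, got %d",
                 idx[which(nf != 3L)[1L]], path, nf[nf != 3L][1L]))
  df <- data.frame(drug_a = trimws(vapply(parts, `[[`, "", 1L)),
                   drug_b = trimws(vapply(parts, `[[`, "", 2L)),
                   type   = trimws(vapply(parts, `[[`, "", 3L)))
  bad <- !(df$type %in% alphabet$labels)
  if (any(bad))
    stop(sprintf("unknown type label '%s' at line %d of %s",
                 df$type[bad][1L], idx[bad][1L], path))
  interaction_network(df, alphabet)
}

#' Write an interaction network to an edge-list file
#'
#' Writes the tab-separated edge-list format of [read_network()], with
#' header comments declaring the alphabet, so that
#' `read_network(path)` round-trips to an equal network.
#'
#' @param net an [interaction_network()].
#' @param path writable file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("# alphabet: ", paste(net$alphabet$labels,
                                            collapse = ",")),
               paste0("# ordered: ",
                      if (net$alphabet$ordered) "true" else "false"),
               paste0("# drugs: ", paste(net$drugs, collapse = ","))),
             con)
  if (nrow(net$obs))
    writeLines(paste(net$obs$a, net$obs$b,
                     net$alphabet$labels[net$obs$type], sep = "\t"), con)
  invisible(path)
}

#' Difference between two snapshots of a network
#'
#' Compares two snapshots of the same (binary) interaction network,
#' restricted to the drugs present in both, and splits all shared-drug
#' pairs into four disjoint sets: `persistent` (edge in both), `novel`
#' (edge only in the second snapshot), `spurious` (edge only in the
#' first), and `never_added` (edge in neither).  Any stored pair counts as
#' an edge; for binary networks built by this package only positive
#' ("interaction") pairs are stored.
#'
#' @param net1,net2 two [interaction_network()]s (the earlier and later
#'   snapshot).
#' @return An object of class `snapshot_diff`: a list of four two-column
#'   character matrices plus `drugs`, the shared drug set.
#' @export
diff_snapshots <- function(net1, net2) {
  shared <- intersect(net1$drugs, net2$drugs)
  if (!length(shared))
    stop("snapshots share no drugs; cannot diff")
  shared <- sort(shared)
  key <- function(net) {
    o <- net$obs[net$obs$a %in% shared & net$obs$b %in% shared, , drop = FALSE]
    ia <- match(o$a, shared); ib <- match(o$b, shared)
    sw <- ia > ib
    tmp <- ia[sw]; ia[sw] <- ib[sw]; ib[sw] <- tmp
    paste(ia, ib)
  }
  unkey <- function(k) {
    if (!length(k)) return(matrix(character(), 0L, 2L))
    ij <- do.call(rbind, strsplit(k, " "))
    cbind(shared[as.integer(ij[, 1L])], shared[as.integer(ij[, 2L])])
  }
  e1 <- key(net1); e2 <- key(net2)
  ij <- combn(seq_along(shared), 2L)
  allk <- paste(ij[1L, ], ij[2L, ])
  res <- list(persistent = unkey(intersect(e1, e2)),
              novel = unkey(setdiff(e2, e1)),
              spurious = unkey(setdiff(e1, e2)),
              never_added = unkey(setdiff(allk, union(e1, e2))),
              drugs = shared)
  class(res) <- "snapshot_diff"
  res
}

#' @export
print.snapshot_diff <- function(x, ...) {
  cat("Snapshot diff over", length(x$drugs), "shared drugs:",
      nrow(x$persistent), "persistent,", nrow(x$novel), "novel,",
      nrow(x$spurious), "spurious,", nrow(x$never_added), "never added\n")
  invisible(x)
}
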