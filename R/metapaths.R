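#' Enumerate the multi-scale meta-path set of a node type
#'
#' A meta-path of order `k` is a typed node sequence of length `k + 1` over
#' the two node types of the heterogeeous network, drug (`r`) and disease
#' (`d`).  The order-`k` set of a start type contains all `2^k` type strings
#' beginning with that type, e.g. order 1 for drugs is `rr, rd` and order 2 is
#' `rrr, rrd, rdr, rdd`.  Paths are returned in canonical order: the start
#' type's own letter sorts before the other letter at every position.
#'
#' @param start_type `"drug"` or `"disease"`.
#' @param k meta-path order (number of edges), an integer `>= 1`.
#' @return character vector of `2^k` type strings, each of length `k + 1`.
#' @examples
#' metapath_set("drug", 1)   # "rr" "rd"
#' metapath_set("drug", 2)   # "rrr" "rrd" "rdr" "rdd"
#' @export
metapath_set <- function(start_type = c("drug", "disease"), k) {
  start_type <- match.arg(start_type)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("`k` must be an integer >= 1")
  first <- if (start_type == "drug") "r" else "d"
  other <- if (first == "r") "d" else "r"
  paths <- first
  for (i in seq_len(k))
    paths <- as.vector(t(outer(paths, c(first, other), paste0)))
  paths
}

#' Extract retained meta-path neighbor sets for every node
#'
#' For each node of a heterogeneous network and each order `k = 1..k_max`,
#' finds the nodes reachable by at least one order-`k` meta-path whose every
#' step traverses a nonzero edge, and retains the top `n_keep[k]` of each
#' neighbor type:
#'
#' * same-type neighbors are ranked by their direct similarity to the node
#'   (the corresponding entry of `u`), descending;
#' * cross-type neighbors are ranked by the number of distinct meta-path
#'   walks reaching them, descending.
#'
#' Ties are broken by node index ascending, so the extraction is
#' deterministic.  At order 1 the node itself heads its own same-type list
#' (followed by the top `n_keep[1] - 1` others); at every order the node is
#' excluded from its candidate sets, and self-loops (the unit diagonal of the
#' similarity blocks) are ignored during walk traversal.  Walks may revisit
#' nodes.  An isolated node keeps `{self}` as its order-1 same-type list and
#' empty lists otherwise, with a warning.
#'
#' @param u heterogeneous network matrix from [hetero_network()].
#' @param k_max largest meta-path order (default 2).
#' @param n_keep integer vector of length `k_max`: how many neighbors to
#'   retain per type at each order.
#' @return an object of class `"neighbor_sets"`: a list with elements `drug`
#'   and `disease`, each a list over orders; element `[[k]]` holds parallel
#'   lists `same`, `cross` (per-node integer index vectors, type-local
#'   indexing) and `same_score`, `cross_score` (the ranking scores, for audit).
#' @export
neighbor_sets <- function(u, k_max = 2L, n_keep = c(10L, 20L)) {
  nr <- attr(u, "n_drugs")
  if (is.null(nr)) stop("`u` must carry an `n_drugs` attribute (see hetero_network())")
  nd <- nrow(u) - nr
  if (length(n_keep) != k_max) stop("`n_keep` must have one entry per order")
  if (any(n_keep < 1)) stop("`n_keep` entries must be >= 1")

  rb <- (u[seq_len(nr), seq_len(nr), drop = FALSE] > 0) * 1; diag(rb) <- 0
  db <- (u[nr + seq_len(nd), nr + seq_len(nd), drop = FALSE] > 0) * 1; diag(db) <- 0
  ab <- (u[seq_len(nr), nr + seq_len(nd), drop = FALSE] > 0) * 1

  walk_counts <- function(start = c("drug", "disease")) {
    # counts[[k]] = list(r = starts x drugs, d = starts x diseases)
    start <- match.arg(start)
    if (start == "drug") {
      cr <- diag(1, nr); cd <- matrix(0, nr, nd)
    } else {
      cr <- matrix(0, nd, nr); cd <- diag(1, nd)
    }
    out <- vector("list", k_max)
    for (k in seq_len(k_max)) {
      cr2 <- cr %*% rb + cd %*% t(ab)
      cd2 <- cr %*% ab + cd %*% db
      cr <- cr2; cd <- cd2
      out[[k]] <- list(r = cr, d = cd)
    }
    out
  }

  rank_top <- function(scores, keep, exclude = 0L) {
    cand <- which(scores > 0)
    cand <- setdiff(cand, exclude)
    if (!length(cand)) return(integer(0))
    cand <- cand[order(-scores[cand], cand)]
    cand[seq_len(min(keep, length(cand)))]
  }

  extract_type <- function(start) {
    wc <- walk_counts(start)
    n_start <- if (start == "drug") nr else nd
    same_key <- if (start == "drug") "r" else "d"
    cross_key <- if (start == "drug") "d" else "r"
    sim_block <- if (start == "drug") u[seq_len(nr), seq_len(nr), drop = FALSE]
                 else u[nr + seq_len(nd), nr + seq_len(nd), drop = FALSE]
    isolated <- logical(n_start)
    per_k <- vector("list", k_max)
    for (k in seq_len(k_max)) {
      same <- cross <- same_score <- cross_score <- vector("list", n_start)
      for (v in seq_len(n_start)) {
        # same-type ranking is by direct similarity; walk counts gate candidacy
        sc <- setdiff(which(wc[[k]][[same_key]][v, ] > 0), v)
        if (length(sc)) {
          sc <- sc[order(-sim_block[v, sc], sc)]
          sc <- sc[seq_len(min(n_keep[k], length(sc)))]
        }
        cc <- rank_top(wc[[k]][[cross_key]][v, ], n_keep[k])
        if (k == 1L) {
          sc <- c(v, sc[seq_len(max(0L, min(length(sc), n_keep[1] - 1L)))])
          if (length(sc) == 1L && !length(cc)) isolated[v] <- TRUE
        }
        same[[v]] <- sc
        cross[[v]] <- cc
        same_score[[v]] <- sim_block[v, sc]
        cross_score[[v]] <- wc[[k]][[cross_key]][v, cc]
      }
      per_k[[k]] <- list(same = same, cross = cross,
                         same_score = same_score, cross_score = cross_score)
    }
    if (any(isolated))
      warning("isolated ", start, " node(s) with no incident edges: ",
              paste(which(isolated), collapse = ", "))
    per_k
  }

  structure(list(drug = extract_type("drug"),
                 disease = extract_type("disease"),
                 n_drugs = nr, n_diseases = nd,
                 k_max = k_max, n_keep = n_keep),
            class = "neighbor_sets")
}

#' @export
print.neighbor_sets <- function(x, ...) {
  cat("Meta-path neighbor sets:", x$n_drugs, "drugs,", x$n_diseases,
      "diseases; orders 1..", x$k_max, "; retained per type: ",
      paste(x$n_keep, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Export neighbor sets as a long audit table
#'
#' @param x a `"neighbor_sets"` object.
#' @param ... unused.
#' @return data.frame with columns `node_type`, `node`, `order`,
#'   `neighbor_type`, `rank`, `neighbor`, `score`.
#' @export
as.data.frame.neighbor_sets <- function(x, ...) {
  rows <- list()
  for (tp in c("drug", "disease")) {
    same_tp <- tp
    cross_tp <- if (tp == "drug") "disease" else "drug"
    for (k in seq_len(x$k_max)) {
      slot <- x[[tp]][[k]]
      n_start <- if (tp == "drug") x$n_drugs else x$n_diseases
      for (v in seq_len(n_start)) {
        if (length(slot$same[[v]]))
          rows[[length(rows) + 1L]] <- data.frame(
            node_type = tp, node = v, order = k, neighbor_type = same_tp,
            rank = seq_along(slot$same[[v]]), neighbor = slot$same[[v]],
            score = as.numeric(slot$same_score[[v]]))
        if (length(slot$cross[[v]]))
          rows[[length(rows) + 1L]] <- data.frame(
            node_type = tp, node = v, order = k, neighbor_type = cross_tp,
            rank = seq_along(slot$cross[[v]]), neighbor = slot$cross[[v]],
            score = as.numeric(slot$cross_score[[v]]))
      }
    }
  }
  do.call(rbind, rows)
}
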