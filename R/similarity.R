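#' Cosine similarity between the rows of a binary property matrix
#'
#' Computes the pairwise cosine similarity between drugs from a binary
#' drug-by-feature incidence matrix (chemical substructures, target-protein
#' domains or target-protein GO terms).  Two drugs sharing many features
#' receive a similarity close to 1; drugs with disjoint feature sets receive 0.
#'
#' A drug whose property row is all zeros has no defined angle with any other
#' drug; by convention it gets similarity 0 to every other drug and 1 to
#' itself, and a warning names the offending drug(s).
#'
#' @param x binary numeric matrix (drugs in rows, features in columns);
#'   row names are used as node labels of the result.
#' @return symmetric numeric matrix with entries in `[0, 1]` and unit
#'   diagonal, with row/column names taken from `rownames(x)`.
#' @examples
#' m <- rbind(a = c(1, 1, 0), b = c(1, 0, 1))
#' cosine_similarity(m)
#' @export
cosine_similarity <- function(x) {
  x <- as.matrix(x)
  check_binary_matrix(x, "property matrix")
  nrm <- sqrt(rowSums(x^2))
  zero <- nrm == 0
  if (any(zero)) {
    who <- if (is.null(rownames(x))) which(zero) else rownames(x)[zero]
    warning("all-zero property row(s) for drug(s): ",
            paste(who, collapse = ", "),
            "; similarity set to 0 (1 to self) by convention")
  }
  nrm[zero] <- 1  # avoid 0/0; affected rows are all-zero so dot products are 0
  s <- tcrossprod(x / nrm)
  diag(s) <- 1
  s[s < 0] <- 0
  s[s > 1] <- 1
  dimnames(s) <- list(rownames(x), rownames(x))
  s
}

#' Disease semantic similarity over term DAGs (Wang method)
#'
#' Each disease is described by the set of semantic terms in its directed
#' acyclic graph, with the disease's own term at depth 0.  The semantic
#' contribution of term `t` to disease `d` decays with depth,
#' `S_d(t) = decay^depth(t)`; the semantic value of a disease is
#' `DV(d) = sum_t S_d(t)`, and the similarity of two diseases is the summed
#' contribution of their shared terms normalized by their semantic values:
#' `sim(d1, d2) = sum_{t in shared} (S_d1(t) + S_d2(t)) / (DV(d1) + DV(d2))`.
#'
#' @param dags named list with one element per disease: a named numeric vector
#'   mapping term ids to integer depths (the disease's own term at depth 0).
#'   See [read_dag()] for the on-disk formats.
#' @param decay semantic decay factor per DAG layer, in `(0, 1)`; the standard
#'   value of the method is 0.5.
#' @param diseases optional character vector selecting/ordering the diseases;
#'   ids absent from `dags` raise an error naming them.
#' @return symmetric similarity matrix with unit diagonal, entries in `[0, 1]`.
#' @examples
#' dags <- list(A = c(A = 0), B = c(B = 0, A = 1))
#' dag_similarity(dags, decay = 0.5)["A", "B"]  # (1 + 0.5) / (1 + 1.5) = 0.6
#' @export
dag_similarity <- function(dags, decay = 0.5, diseases = NULL) {
  if (!is.numeric(decay) || length(decay) != 1L || decay <= 0 || decay >= 1)
    stop("`decay` must be a single number in (0, 1)")
  if (is.null(diseases)) diseases <- names(dags)
  if (is.null(diseases)) stop("`dags` must be a named list")
  missing_ids <- setdiff(diseases, names(dags))
  if (length(missing_ids))
    stop("disease(s) absent from the DAG collection: ",
         paste(missing_ids, collapse = ", "))
  dags <- dags[diseases]
  bad <- vapply(dags, function(d) length(d) == 0L, logical(1))
  if (any(bad))
    stop("empty DAG for disease(s): ", paste(diseases[bad], collapse = ", "))
  contrib <- lapply(dags, function(d) decay^d)  # named: term -> contribution
  dv <- vapply(contrib, sum, numeric(1))
  n <- length(dags)
  s <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      ci <- contrib[[i]]
      for (j in seq.int(i + 1L, n)) {
        cj <- contrib[[j]]
        shared <- intersect(names(ci), names(cj))
        if (length(shared))
          s[i, j] <- s[j, i] <-
            (sum(ci[shared]) + sum(cj[shared])) / (dv[i] + dv[j])
      }
    }
  }
  dimnames(s) <- list(diseases, diseases)
  s
}

#' Assemble a drug-disease heterogeneous network
#'
#' Builds the square block matrix over drug-then-disease nodes,
#' `U = [[R, A], [A', D]]`, from a drug similarity matrix `R`, the binary
#' drug-disease association matrix `A` and the disease similarity matrix `D`.
#' Zero entries mean "no edge"; any positive similarity or association is an
#' edge weighted by that value.  Three such networks (one per drug similarity
#' view) feed the prediction model.
#'
#' @param drug_sim symmetric drug similarity matrix (`n_drugs` square).
#' @param assoc binary association matrix, drugs in rows, diseases in columns.
#' @param disease_sim symmetric disease similarity matrix (`n_diseases` square).
#' @return a `(n_drugs + n_diseases)` square symmetric matrix with an
#'   `n_drugs` attribute recording the size of the drug block; drug nodes come
#'   first in the ordering.
#' @export
hetero_network <- function(drug_sim, assoc, disease_sim) {
  drug_sim <- as.matrix(drug_sim)
  assoc <- as.matrix(assoc)
  disease_sim <- as.matrix(disease_sim)
  nr <- nrow(assoc); nd <- ncol(assoc)
  if (!identical(dim(drug_sim), c(nr, nr)))
    stop(sprintf("drug similarity must be %d x %d, got %d x %d",
                 nr, nr, nrow(drug_sim), ncol(drug_sim)))
  if (!identical(dim(disease_sim), c(nd, nd)))
    stop(sprintf("disease similarity must be %d x %d, got %d x %d",
                 nd, nd, nrow(disease_sim), ncol(disease_sim)))
  check_binary_matrix(assoc, "association matrix")
  u <- rbind(cbind(drug_sim, assoc), cbind(t(assoc), disease_sim))
  labs <- c(rownames(assoc) %||% paste0("r", seq_len(nr)),
            colnames(assoc) %||% paste0("d", seq_len(nd)))
  dimnames(u) <- list(labs, labs)
  attr(u, "n_drugs") <- nr
  u
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared validator: entries must be exactly 0/1
check_binary_matrix <- function(x, what) {
  if (!is.numeric(x)) stop(what, " must be numeric")
  if (any(!is.finite(x))) stop(what, " contains non-finite entries")
  if (any(x != 0 & x != 1)) {
    bad <- which(x != 0 & x != 1, arr.ind = TRUE)[1, ]
    stop(sprintf("%s must be binary; entry [%d, %d] is %g",
                 what, bad[1], bad[2], x[bad[1], bad[2]]))
  }
  invisible(TRUE)
}
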