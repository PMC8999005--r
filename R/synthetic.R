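#' Simulate a drug-disease dataset with planted low-rank association structure
#'
#' Generates the complete set of model inputs — three binary drug property
#' matrices, a disease term DAG collection and a binary association matrix —
#' with a known latent structure so that recovery can be measured.  Drugs and
#' diseases are assigned to `rank` latent clusters; each entity's latent
#' vector is its cluster indicator plus Gaussian jitter.  Property features
#' are organized in per-cluster blocks (a drug carries its cluster's block,
#' corrupted by Bernoulli bit flips at the `noise` rate), disease DAGs share a
#' per-cluster ancestor chain under a common root (a disease's chain is
#' swapped to a random cluster with probability `noise`), and associations
#' are drawn with probability `sigmoid(steepness * <x_i, y_j> + b)` where the
#' intercept `b` is calibrated by root finding so the expected density matches
#' `density`.
#'
#' @param n_drugs,n_diseases entity counts.
#' @param n_features integer vector of length 3: feature counts of the
#'   chemical-substructure, protein-domain and GO property matrices.
#' @param rank number of latent clusters (`>= 1`).
#' @param density target association density in `(0, 1)`.
#' @param noise property bit-flip and DAG cluster-swap probability.
#' @param steepness slope of the association sigmoid on the latent dot
#'   product; larger values plant a crisper signal.
#' @param jitter standard deviation of the latent Gaussian jitter.
#' @param chain_depth length of each cluster's DAG ancestor chain.
#' @param seed optional integer seed; identical seeds give byte-identical
#'   datasets.
#' @return an object of class `"dd_data"`: list with `properties` (list of 3
#'   binary matrices), `dags`, `assoc`, and `latent` (ground-truth factors
#'   `drug`, `disease` and the association probability matrix, for audit).
#' @export
simulate_dd_data <- function(n_drugs = 60L, n_diseases = 50L,
                             n_features = c(80L, 100L, 120L), rank = 3L,
                             density = 0.05, noise = 0.1, steepness = 12,
                             jitter = 0.15, chain_depth = 3L, seed = NULL) {
  if (density <= 0 || density >= 1) stop("`density` must be in (0, 1)")
  if (rank < 1) stop("`rank` must be >= 1")
  if (any(c(n_drugs, n_diseases, n_features) < 1)) stop("all counts must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  drug_ids <- sprintf("drug%03d", seq_len(n_drugs))
  dis_ids <- sprintf("dis%03d", seq_len(n_diseases))
  drug_cl <- sample(rep_len(seq_len(rank), n_drugs))
  dis_cl <- sample(rep_len(seq_len(rank), n_diseases))
  lat <- function(cl) {
    x <- matrix(stats::rnorm(length(cl) * rank, sd = jitter), length(cl), rank)
    x[cbind(seq_along(cl), cl)] <- x[cbind(seq_along(cl), cl)] + 1
    x
  }
  x_drug <- lat(drug_cl); x_dis <- lat(dis_cl)

  make_props <- function(nf, fid_prefix) {
    blocks <- rep_len(seq_len(rank), nf)          # feature -> cluster block
    base <- outer(drug_cl, blocks, `==`) * 1
    flip <- matrix(stats::rbinom(n_drugs * nf, 1, noise), n_drugs, nf)
    m <- abs(base - flip)
    dimnames(m) <- list(drug_ids, paste0(fid_prefix, seq_len(nf)))
    m
  }
  properties <- list(chem = make_props(n_features[1], "c"),
                     domain = make_props(n_features[2], "p"),
                     go = make_props(n_features[3], "g"))

  dag_cl <- ifelse(stats::runif(n_diseases) < noise,
                   sample.int(rank, n_diseases, replace = TRUE), dis_cl)
  dags <- lapply(seq_len(n_diseases), function(j) {
    chain <- sprintf("CL%d_T%d", dag_cl[j], seq_len(chain_depth))
    stats::setNames(c(0, seq_len(chain_depth), chain_depth + 1),
                    c(dis_ids[j], rev(chain), "ROOT"))
  })
  names(dags) <- dis_ids

  dot <- x_drug %*% t(x_dis)
  bias <- stats::uniroot(function(b) mean(stats::plogis(steepness * dot + b)) - density,
                         c(-100, 100), tol = 1e-10)$root
  prob <- stats::plogis(steepness * dot + bias)
  assoc <- matrix(as.numeric(stats::rbinom(length(prob), 1, prob)),
                  n_drugs, n_diseases, dimnames = list(drug_ids, dis_ids))

  structure(list(properties = properties, dags = dags, assoc = assoc,
                 latent = list(drug = x_drug, disease = x_dis, prob = prob,
                               drug_cluster = drug_cl, disease_cluster = dis_cl),
                 spec = list(n_drugs = n_drugs, n_diseases = n_diseases,
                             n_features = n_features, rank = rank,
                             density = density, noise = noise,
                             steepness = steepness, jitter = jitter,
                             chain_depth = chain_depth, seed = seed)),
            class = "dd_data")
}

#' @export
print.dd_data <- function(x, ...) {
  cat("Synthetic drug-disease dataset:", x$spec$n_drugs, "drugs,",
      x$spec$n_diseases, "diseases,", sum(x$assoc), "associations (density",
      sprintf("%.3f", mean(x$assoc)), ")\n")
  cat("Property features:", paste(x$spec$n_features, collapse = "/"),
      "; latent rank", x$spec$rank, "; noise", x$spec$noise, "\n")
  invisible(x)
}

#' Write a simulated dataset to disk in the package's TSV formats
#'
#' Writes `chem.tsv`, `domain.tsv`, `go.tsv` (binary property matrices),
#' `assoc.tsv` (association matrix) and `dag.tsv` (per-disease term\@depth
#' list), plus `latent_drug.tsv` / `latent_disease.tsv` with the ground-truth
#' factors for audit.  Files round-trip exactly through [read_dd_data()].
#'
#' @param data a `"dd_data"` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dd_data <- function(data, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  write_matrix(data$properties$chem, file.path(dir, "chem.tsv"))
  write_matrix(data$properties$domain, file.path(dir, "domain.tsv"))
  write_matrix(data$properties$go, file.path(dir, "go.tsv"))
  write_matrix(data$assoc, file.path(dir, "assoc.tsv"))
  write_dag(data$dags, file.path(dir, "dag.tsv"))
  lat_d <- data$latent$drug; rownames(lat_d) <- rownames(data$assoc)
  lat_s <- data$latent$disease; rownames(lat_s) <- colnames(data$assoc)
  colnames(lat_d) <- colnames(lat_s) <- paste0("f", seq_len(ncol(lat_d)))
  write_matrix(lat_d, file.path(dir, "latent_drug.tsv"))
  write_matrix(lat_s, file.path(dir, "latent_disease.tsv"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dd_data()]
#'
#' @param dir directory containing the TSV files.
#' @return list with `properties`, `dags`, `assoc` (and `latent` factors when
#'   present).
#' @export
read_dd_data <- function(dir) {
  out <- list(
    properties = list(chem = read_matrix(file.path(dir, "chem.tsv"), "binary"),
                      domain = read_matrix(file.path(dir, "domain.tsv"), "binary"),
                      go = read_matrix(file.path(dir, "go.tsv"), "binary")),
    dags = read_dag(file.path(dir, "dag.tsv")),
    assoc = read_matrix(file.path(dir, "assoc.tsv"), "binary"))
  for (nm in c("latent_drug", "latent_disease")) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    if (file.exists(f)) out$latent[[sub("latent_", "", nm)]] <- read_matrix(f)
  }
  out
}
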