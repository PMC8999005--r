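# Readers and writers for the package's plain-text formats: labelled TSV/CSV
# matrices (one header row of column ids, one header column of row ids) and
# per-disease DAG term lists.  Validation errors carry file line numbers.

split_fields <- function(lines, sep) strsplit(lines, sep, fixed = TRUE)

sniff_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a labelled matrix from TSV/CSV
#'
#' Expects one header row of column labels and one header column of row
#' labels (top-left cell ignored).  Ragged rows, non-numeric or missing
#' cells and duplicate labels are hard errors naming the offending line;
#' `kind = "binary"` additionally requires every entry to be 0 or 1.
#'
#' @param path file path; `.csv` extension switches the separator to a comma.
#' @param kind `"numeric"` or `"binary"`.
#' @return numeric matrix with row/column names.
#' @export
read_matrix <- function(path, kind = c("numeric", "binary")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sniff_sep(path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop(path, ": need a header row and at least one data row")
  fields <- split_fields(lines, sep)
  header <- fields[[1]]
  ncol_data <- length(header) - 1L
  if (ncol_data < 1) stop(path, ": header row has no column labels")
  col_ids <- header[-1]
  if (anyDuplicated(col_ids)) stop(path, ": duplicate column label(s): ",
                                   paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  n <- length(fields) - 1L
  out <- matrix(NA_real_, n, ncol_data)
  row_ids <- character(n)
  for (r in seq_len(n)) {
    f <- fields[[r + 1L]]
    if (length(f) != ncol_data + 1L)
      stop(sprintf("%s line %d: expected %d fields, found %d",
                   path, r + 1L, ncol_data + 1L, length(f)))
    row_ids[r] <- f[1]
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      stop(sprintf("%s line %d: non-numeric cell '%s' in column %s",
                   path, r + 1L, f[bad + 1L], col_ids[bad]))
    }
    out[r, ] <- vals
  }
  if (anyDuplicated(row_ids)) stop(path, ": duplicate row label(s): ",
                                   paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  dimnames(out) <- list(row_ids, col_ids)
  if (kind == "binary" && any(out != 0 & out != 1)) {
    bad <- which(out != 0 & out != 1, arr.ind = TRUE)[1, ]
    stop(sprintf("%s: binary matrix has value %g at row %s, column %s",
                 path, out[bad[1], bad[2]], row_ids[bad[1]], col_ids[bad[2]]))
  }
  out
}

#' Write a labelled matrix as TSV/CSV
#'
#' @param x matrix with row and column names.
#' @param path output path; `.csv` writes comma-separated.
#' @export
write_matrix <- function(x, path) {
  sep <- sniff_sep(path)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("matrix must have row and column names")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(x)), collapse = sep), con)
  body <- apply(x, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE,
                                               digits = 15), collapse = sep))
  writeLines(paste(rownames(x), body, sep = sep), con)
  invisible(path)
}

#' Read disease DAGs from TSV
#'
#' Two formats are supported, distinguished by the header:
#'
#' * term-depth list: columns `disease_id`, `term_id`, `depth` — each row
#'   assigns one term (with its layer depth) to one disease's DAG; the
#'   disease's own term must appear at depth 0;
#' * edge list: columns `disease_id`, `term_id`, `parent_term_id` — each
#'   disease's rows are child-parent edges; the disease's own term is the
#'   term equal to `disease_id`, and depths are shortest ancestor-path
#'   lengths from it.
#'
#' @param path file path.
#' @return named list: per disease, a named numeric vector mapping term ids
#'   to depths.
#' @export
read_dag <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sniff_sep(path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- split_fields(lines, sep)
  header <- fields[[1]]
  if (length(header) != 3)
    stop(path, ": DAG file must have exactly 3 columns, found ", length(header))
  body <- fields[-1]
  bad <- which(lengths(body) != 3L)
  if (length(bad))
    stop(sprintf("%s line %d: expected 3 fields, found %d",
                 path, bad[1] + 1L, lengths(body)[bad[1]]))
  d <- data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  names(d) <- header
  if (identical(header[3], "depth")) {
    depth <- suppressWarnings(as.numeric(d$depth))
    if (anyNA(depth))
      stop(sprintf("%s line %d: non-numeric depth '%s'",
                   path, which(is.na(depth))[1] + 1L, d$depth[which(is.na(depth))[1]]))
    out <- lapply(split(seq_len(nrow(d)), factor(d$disease_id, unique(d$disease_id))),
                  function(i) stats::setNames(depth[i], d$term_id[i]))
    for (nm in names(out))
      if (!any(out[[nm]] == 0))
        stop(path, ": disease ", nm, " has no depth-0 term")
    out
  } else if (identical(header[3], "parent_term_id")) {
    out <- lapply(split(seq_len(nrow(d)), factor(d$disease_id, unique(d$disease_id))),
                  function(i) dag_depths_from_edges(d$term_id[i], d$parent_term_id[i],
                                                    d$disease_id[i][1]))
    out
  } else {
    stop(path, ": third column must be 'depth' or 'parent_term_id', found '",
         header[3], "'")
  }
}

# BFS depths over child->parent edges starting from the disease's own term
dag_depths_from_edges <- function(child, parent, disease_id) {
  terms <- unique(c(child, parent))
  if (!disease_id %in% terms)
    stop("disease ", disease_id, " has no own term among its DAG edges")
  depth <- stats::setNames(rep(NA_real_, length(terms)), terms)
  depth[disease_id] <- 0
  frontier <- disease_id
  while (length(frontier)) {
    nxt <- character(0)
    for (t in frontier) {
      pars <- parent[child == t]
      new <- pars[is.na(depth[pars])]
      depth[new] <- depth[t] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  depth[!is.na(depth)]
}

#' Write disease DAGs as a term-depth TSV
#'
#' @param dags named list of named depth vectors (see [read_dag()]).
#' @param path output path.
#' @export
write_dag <- function(dags, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("disease_id\tterm_id\tdepth", con)
  for (nm in names(dags))
    writeLines(paste(nm, names(dags[[nm]]), format(dags[[nm]], trim = TRUE),
                     sep = "\t"), con)
  invisible(path)
}

#' Load and validate a YAML run configuration
#'
#' Reads a YAML file whose keys are arguments of [dd_control()] plus the
#' optional keys `seed` and `decay`; unknown keys are rejected, all values
#' are validated, and defaults fill the rest.  An empty/missing-key file
#' yields the documented defaults.
#'
#' @param path YAML file path.
#' @return list with `control` (a validated [dd_control()] list), `seed` and
#'   `decay`.
#' @export
load_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  extra_keys <- c("seed", "decay")
  known <- c(names(formals(dd_control)), extra_keys)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown configuration key(s): ",
                            paste(unknown, collapse = ", "))
  control <- do.call(dd_control, cfg[setdiff(names(cfg), extra_keys)])
  decay <- cfg$decay %||% 0.5
  if (!is.numeric(decay) || decay <= 0 || decay >= 1)
    stop("`decay` must be in (0, 1)")
  list(control = control, seed = cfg$seed, decay = decay)
}
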