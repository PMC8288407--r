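#' Build a centroid reference for cell-type projection
#'
#' Features are the union of the top per-type genes ranked by one-vs-rest
#' q-value (taken from [find_signatures()]'s underlying test table, so a
#' reference can be built even when few genes pass the signature
#' thresholds); each type's centroid is its per-gene mean normalized
#' expression over the features.  Means, not medians: for sparse
#' log-normalized UMI data the per-gene median is bistable wherever a
#' gene's detection rate sits near 50% (it flips between 0 and the
#' one-count value across resamples), which injects large noise into
#' every centroid; the mean is smooth, and the log transform already
#' tempers outliers.
#'
#' @param norm Normalized cells x genes matrix.
#' @param cells Cell metadata aligned with the rows (>= 2 types with >= 3
#'   cells each).
#' @param n_features Total feature budget; split evenly across types
#'   (default 1000, roughly the number of cell types times the expected
#'   signature count per type).  A value above the gene count uses every
#'   gene, with a warning.
#' @param similarity_threshold Default cosine threshold stored in the
#'   model (see [project_cells()]).
#' @return List of class `abc_reference`: `features`, `centroids`
#'   (types x features, non-negative), `similarity_threshold`.
#' @export
build_reference <- function(norm, cells, n_features = 1000L,
                            similarity_threshold = 0.7) {
  all_genes <- FALSE
  if (n_features >= ncol(norm)) {
    if (n_features > ncol(norm))
      warning("n_features exceeds gene count; using all ", ncol(norm),
              " genes")
    n_features <- ncol(norm)
    all_genes <- TRUE
  }
  tab <- .ovr_table(norm, cells)
  types <- unique(tab$cell_type)
  feats <- if (all_genes) colnames(norm) else {
    per <- max(1L, ceiling(n_features / length(types)))
    unique(unlist(lapply(split(tab, tab$cell_type), function(d) {
      d <- d[order(d$q, -d$log2fc), ]
      utils::head(d$gene_id, per)
    }), use.names = FALSE))
  }
  if (length(feats) < 10L) {     # degenerate fallback: overall best genes
    extra <- tab$gene_id[order(tab$q)]
    feats <- utils::head(unique(c(feats, extra)), max(10L, n_features))
  }
  cent <- t(vapply(types, function(ct) {
    colMeans(norm[cells$cell_type == ct, feats, drop = FALSE])
  }, numeric(length(feats))))
  dimnames(cent) <- list(types, feats)
  if (any(rowSums(cent) == 0))
    stop("all-zero centroid for type(s): ",
         paste(types[rowSums(cent) == 0], collapse = ", "))
  structure(list(features = feats, centroids = cent,
                 similarity_threshold = similarity_threshold),
            class = "abc_reference")
}

#' Project query cells onto a centroid reference
#'
#' Cosine similarity of every query cell to every centroid over the
#' shared features; a cell is assigned the arg-max type when the maximal
#' similarity reaches the threshold, else `"UNASSIGNED"`.  Ties are
#' broken by the reference's fixed type order and reported.
#'
#' @param query Normalized cells x genes matrix; its genes must cover at
#'   least 50% of the reference features (fewer is an error).
#' @param ref `abc_reference` from [build_reference()].
#' @param threshold Cosine similarity threshold (default: the one stored
#'   in the reference).
#' @return `data.frame` with `cell_id`, `assigned_type`, `similarity`
#'   (max cosine), `tie` (logical).
#' @export
project_cells <- function(query, ref, threshold = ref$similarity_threshold) {
  shared <- intersect(colnames(query), ref$features)
  if (!length(shared)) stop("no feature shared between query and reference")
  if (length(shared) < 0.5 * length(ref$features))
    stop("query covers only ", length(shared), "/", length(ref$features),
         " reference features (< 50%)")
  Q <- query[, shared, drop = FALSE]
  C <- ref$centroids[, shared, drop = FALSE]
  qn <- sqrt(rowSums(Q^2)); cn <- sqrt(rowSums(C^2))
  sim <- (Q %*% t(C)) / outer(pmax(qn, .Machine$double.eps),
                              pmax(cn, .Machine$double.eps))
  best <- apply(sim, 1, max)
  pick <- apply(sim, 1, which.max)
  tie <- apply(sim, 1, function(r) sum(r == max(r)) > 1L)
  assigned <- ifelse(best >= threshold, rownames(C)[pick], "UNASSIGNED")
  data.frame(cell_id = rownames(Q) %||% seq_len(nrow(Q)),
             assigned_type = assigned,
             similarity = as.numeric(best), tie = tie,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Self-projection accuracy by stratified cross-validation
#'
#' Splits the cells into `n_folds` stratified folds; for each fold a
#' reference is built from the remaining cells and the held-out cells are
#' projected.  Accuracy is correct assignments over all cells, with
#' `UNASSIGNED` counted as incorrect.  Types with fewer than `n_folds`
#' cells are warned about and distributed over the folds (degenerating
#' toward leave-one-out for that type).
#'
#' @inheritParams build_reference
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param threshold Cosine threshold for [project_cells()].
#' @return List with `overall` (accuracy in \[0, 1\]), `per_type`
#'   (`data.frame` with `cell_type`, `n`, `accuracy`), `predictions`.
#' @export
self_projection_accuracy <- function(norm, cells, n_folds = 5L, seed = 1L,
                                     n_features = 1000L, threshold = 0.7) {
  withr::local_seed(seed)
  small <- names(which(table(cells$cell_type) < n_folds))
  if (length(small))
    warning("type(s) with fewer cells than folds: ",
            paste(small, collapse = ", "))
  fold <- integer(nrow(cells))
  for (ct in unique(cells$cell_type)) {
    idx <- which(cells$cell_type == ct)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  preds <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (!any(!tr)) next
    ref <- build_reference(norm[tr, , drop = FALSE],
                           cells[tr, , drop = FALSE],
                           n_features = n_features,
                           similarity_threshold = threshold)
    pr <- project_cells(norm[!tr, , drop = FALSE], ref)
    pr$true_type <- cells$cell_type[!tr]
    preds[[f]] <- pr
  }
  preds <- do.call(rbind, preds)
  correct <- preds$assigned_type == preds$true_type
  sp <- split(correct, preds$true_type)
  per_type <- data.frame(
    cell_type = names(sp),
    n = vapply(sp, length, integer(1)),
    accuracy = vapply(sp, mean, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(per_type) <- NULL
  list(overall = mean(correct), per_type = per_type, predictions = preds)
}
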