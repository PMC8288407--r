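#' Read / write regulons as GMT-like text
#'
#' One regulon per line: the transcription factor name, a tab, then the
#' target gene ids (TF conventionally included among its own targets).
#'
#' @param path File path.
#' @param regulons Named list (TF -> character vector of targets).
#' @return `read_gmt()`: named list of target vectors; `write_gmt()`:
#'   `path`, invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(x) unique(x[-1L])),
                  vapply(parts, `[[`, character(1), 1L))
}

#' @rdname read_gmt
#' @export
write_gmt <- function(regulons, path) {
  writeLines(vapply(names(regulons), function(tf)
    paste(c(tf, regulons[[tf]]), collapse = "\t"), character(1)), path)
  invisible(path)
}

#' Regulon activity score of one regulon across cells
#'
#' Rank-recovery area under the curve: per cell, genes are ranked by
#' decreasing expression (ties broken by fixed gene order); with
#' `X = floor(top_fraction * n_genes)` and recovery curve
#' `r(k) = |targets among top k| / |targets|`, the score is
#' `sum(r(1..X)) / X`, which lies in \[0, 1\] and depends only on the
#' within-cell expression ranks.
#'
#' @param norm Normalized cells x genes matrix.
#' @param targets Character vector of target gene ids (at least one must
#'   resolve against the matrix columns; none resolving is an error).
#' @param top_fraction Fraction of the ranking that defines the "highly
#'   expressed" window (0 < f < 1, default 0.05).
#' @return Numeric vector of per-cell scores.
#' @export
ras_auc <- function(norm, targets, top_fraction = 0.05) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  tidx <- match(unique(targets), colnames(norm))
  tidx <- tidx[!is.na(tidx)]
  if (!length(tidx)) stop("regulon has no target resolvable in the matrix")
  G <- ncol(norm)
  X <- max(1L, floor(top_fraction * G))
  nt <- length(tidx)
  apply(norm, 1, function(x) {
    pos <- integer(G)
    pos[order(-x, seq_len(G))] <- seq_len(G)
    tp <- pos[tidx]
    tp <- tp[tp <= X]
    # sum_k r(k) = sum over recovered targets of (X - pos + 1), / (X * nt)
    sum(X - tp + 1) / (X * nt)
  })
}

#' Regulon activity score matrix
#'
#' Applies [ras_auc()] to every regulon, sharing the per-cell ranking.
#'
#' @param norm Normalized cells x genes matrix.
#' @param regulons Named list (TF -> target ids), e.g. from [read_gmt()].
#' @param top_fraction See [ras_auc()].
#' @param min_targets Regulons with fewer resolvable targets are dropped
#'   with a warning (default 5).
#' @return Cells x regulons matrix of scores in \[0, 1\].
#' @export
ras_scores <- function(norm, regulons, top_fraction = 0.05,
                       min_targets = 5L) {
  G <- ncol(norm)
  X <- max(1L, floor(top_fraction * G))
  tidx <- lapply(regulons, function(tg) {
    i <- match(unique(tg), colnames(norm)); i[!is.na(i)]
  })
  keep <- lengths(tidx) >= min_targets
  if (!any(keep)) stop("no regulon with >= ", min_targets,
                       " resolvable targets")
  if (any(!keep))
    warning("dropping regulon(s) with < ", min_targets, " targets: ",
            paste(names(regulons)[!keep], collapse = ", "))
  tidx <- tidx[keep]
  ras <- matrix(0, nrow(norm), length(tidx),
                dimnames = list(rownames(norm), names(tidx)))
  pos <- integer(G)
  for (c in seq_len(nrow(norm))) {
    pos[order(-norm[c, ], seq_len(G))] <- seq_len(G)
    for (r in seq_along(tidx)) {
      tp <- pos[tidx[[r]]]
      tp <- tp[tp <= X]
      ras[c, r] <- sum(X - tp + 1) / (X * length(tidx[[r]]))
    }
  }
  ras
}

# Deterministic 1-D two-means: centers initialized at the 10th and 90th
# percentiles, Lloyd iterations to convergence.  Returns the midpoint
# threshold, or NA for a (near-)constant vector.
.two_means_threshold <- function(x, tol = 1e-12, max_iter = 100L) {
  if (max(x) - min(x) < tol) return(NA_real_)
  ctr <- unname(stats::quantile(x, c(0.1, 0.9)))
  if (diff(ctr) < tol) ctr <- c(min(x), max(x))
  for (i in seq_len(max_iter)) {
    mid <- mean(ctr)
    lo <- x <= mid
    new <- c(mean(x[lo]), mean(x[!lo]))
    if (max(abs(new - ctr)) < tol) { ctr <- new; break }
    ctr <- new
  }
  mean(ctr)
}

#' Binarize regulon activity scores to on/off
#'
#' Per regulon, a threshold is placed at the midpoint of the two centers
#' found by a deterministic one-dimensional two-means (initialized at the
#' 10th/90th percentiles); a cell is "on" when its score is strictly
#' above the threshold.  Constant columns are dropped with a warning.
#' The result is invariant to cell order.
#'
#' @param ras Cells x regulons score matrix (>= 10 cells).
#' @return List of class `ras_binary`: `state` (binary cells x regulons
#'   matrix) and `thresholds` (named, each strictly between the observed
#'   min and max of its column).
#' @export
binarize_ras <- function(ras) {
  if (nrow(ras) < 10L) stop("need >= 10 cells to binarize")
  thr <- vapply(seq_len(ncol(ras)), function(j)
    .two_means_threshold(ras[, j]), numeric(1))
  names(thr) <- colnames(ras)
  drop <- is.na(thr)
  if (any(drop))
    warning("dropping constant-score regulon(s): ",
            paste(colnames(ras)[drop], collapse = ", "))
  keep <- which(!drop)
  state <- ras[, keep, drop = FALSE] >
    matrix(thr[keep], nrow(ras), length(keep), byrow = TRUE)
  storage.mode(state) <- "integer"
  structure(list(state = state, thresholds = thr[keep]),
            class = "ras_binary")
}

#' Cluster-level regulon on/off states
#'
#' A regulon is "on" in a cluster when at least `min_on_fraction` of the
#' cluster's cells are on.  A regulon is *specific* to a cluster when it
#' is on there and on in fewer than `max_other` other clusters.
#'
#' @param binary `ras_binary` from [binarize_ras()] (or a plain binary
#'   cells x regulons matrix).
#' @param cluster_labels Cluster label per cell (no empty clusters; every
#'   cell labeled).
#' @param min_on_fraction On-state threshold (default 0.5).
#' @param max_other Specificity cut-off `k`: specific regulons are on in
#'   `< k` clusters other than the focal one (default 2).
#' @return List of class `regulon_states`: `state` (clusters x regulons
#'   binary matrix), `on_fraction`, `specific` (named list cluster ->
#'   specific regulon names).
#' @export
cluster_regulon_states <- function(binary, cluster_labels,
                                   min_on_fraction = 0.5, max_other = 2L) {
  if (inherits(binary, "ras_binary")) binary <- binary$state
  if (anyNA(cluster_labels) || length(cluster_labels) != nrow(binary))
    stop("every cell must carry a cluster label")
  grp <- factor(cluster_labels)
  if (any(table(grp) == 0L)) stop("empty cluster(s)")
  frac <- rowsum(binary, grp) / as.vector(table(grp))
  state <- (frac >= min_on_fraction) + 0L
  n_on <- colSums(state)
  specific <- lapply(rownames(state), function(cl) {
    colnames(state)[state[cl, ] == 1L & (n_on - 1L) < max_other]
  })
  names(specific) <- rownames(state)
  structure(list(state = state, on_fraction = frac, specific = specific),
            class = "regulon_states")
}

#' Flag regulons whose TF is absent from a canonical list
#'
#' Novel regulons are those activated (on) in at least one cluster whose
#' transcription factor — the regulon's name — is not in the supplied
#' canonical transcription-factor list.  A curated list of canonical
#' human hematopoietic TFs ships with the package
#' (`system.file("extdata", "canonical_tfs_hematopoiesis.txt",
#' package = "bloodatlas")`).
#'
#' @param states `regulon_states` from [cluster_regulon_states()].
#' @param canonical_tfs Character vector of canonical TF gene ids.
#' @return Character vector of novel regulon names (possibly empty).
#' @export
flag_novel_regulons <- function(states, canonical_tfs) {
  activated <- colnames(states$state)[colSums(states$state) >= 1L]
  sort(setdiff(activated, canonical_tfs))
}
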