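# Column-wise midranks and tie terms for a cells x genes matrix, computed
# with a single radix sort over the whole matrix (fast enough to be run
# once per cell-type pair in pairwise DEG counting).
.col_ranks <- function(X) {
  n <- nrow(X); G <- ncol(X)
  colv <- rep(seq_len(G), each = n)
  o <- order(colv, as.vector(X))
  v <- as.vector(X)[o]
  oc <- colv            # already sorted primary key: colv[o] == colv
  newrun <- c(TRUE, v[-1L] != v[-length(v)])
  newrun[seq(1L, n * G, by = n)] <- TRUE  # new column starts a new run
  run <- cumsum(newrun)
  len <- tabulate(run)
  pos_in_col <- rep(seq_len(n), G)
  start_pos <- pos_in_col[newrun]
  avg <- rep(start_pos + (len - 1) / 2, len)
  R <- matrix(0, n, G, dimnames = dimnames(X))
  R[o] <- avg
  tie_contrib <- len^3 - len
  tie <- as.vector(rowsum(tie_contrib, oc[newrun], reorder = TRUE))
  list(R = R, tie = tie)
}

# One-vs-rest (or group-vs-group) Wilcoxon statistics for every gene.
# Normal approximation with tie and continuity correction; the group
# sizes in signature calling are large enough for it (the exact small-
# sample path lives in rank_sum_test()).
.wilcox_genes <- function(R, tie, in_idx) {
  n <- nrow(R)
  n1 <- sum(in_idx); n2 <- n - n1
  W1 <- colSums(R[in_idx, , drop = FALSE])
  U <- W1 - n1 * (n1 + 1) / 2
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie / (n * (n - 1))))
  z <- U - n1 * n2 / 2
  zc <- (z - sign(z) * 0.5) / sigma
  p <- 2 * stats::pnorm(-abs(zc))
  p[sigma == 0] <- 1
  pmin(p, 1)
}

# log2 fold change on de-logged means: normalized values v = log2(t + 1)
# with t = TPM/10, so means are taken on 2^v - 1 with a small pseudocount.
.log2fc <- function(norm, in_idx, eps = 1e-9) {
  expm <- 2^norm - 1
  m_in <- colMeans(expm[in_idx, , drop = FALSE])
  m_out <- colMeans(expm[!in_idx, , drop = FALSE])
  log2((m_in + eps) / (m_out + eps))
}

#' Call per-cell-type signature genes
#'
#' One-vs-rest Wilcoxon rank-sum test per gene per cell type on the
#' normalized matrix, with Benjamini-Hochberg correction within each
#' type.  A gene is a signature of a type when `q <= max_q`,
#' `log2FC >= min_lfc` (computed on de-logged means with pseudocount
#' 1e-9) and it is detected in at least `min_pct_in` of the type's cells.
#' `mode = "top_n"` instead keeps the `top_n` genes with smallest q
#' (ties by fold change) among those with positive fold change.
#'
#' @param norm Normalized cells x genes matrix ([normalize_log2tpm10()]).
#' @param cells Cell metadata aligned with the rows of `norm`.
#' @param min_lfc,max_q,min_pct_in Signature thresholds (defaults 1, 0.05,
#'   0.25).
#' @param mode `"threshold"` (default) or `"top_n"`.
#' @param top_n Number of genes per type in `"top_n"` mode.
#' @return `data.frame` of class `signature_set` with columns `cell_type`,
#'   `gene_id`, `log2fc`, `p`, `q`, `pct_in`, `pct_out`, sorted within
#'   type by `q` then decreasing `log2fc`.  Types with fewer than 3 cells
#'   are skipped with a warning.
#' @export
find_signatures <- function(norm, cells, min_lfc = 1, max_q = 0.05,
                            min_pct_in = 0.25,
                            mode = c("threshold", "top_n"), top_n = 50L) {
  mode <- match.arg(mode)
  stopifnot(nrow(norm) == nrow(cells))
  tab <- .ovr_table(norm, cells)
  res <- lapply(split(tab, tab$cell_type), function(d) {
    if (mode == "threshold") {
      d <- d[d$q <= max_q & d$log2fc >= min_lfc & d$pct_in >= min_pct_in, ,
             drop = FALSE]
    } else {
      d <- d[d$log2fc > 0, , drop = FALSE]
      d <- d[order(d$q, -d$log2fc), , drop = FALSE]
      d <- utils::head(d, top_n)
    }
    d[order(d$q, -d$log2fc), , drop = FALSE]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("signature_set", "data.frame")
  out
}

# Full one-vs-rest test table over all genes and all usable types.
.ovr_table <- function(norm, cells) {
  types <- unique(cells$cell_type)
  sizes <- table(cells$cell_type)[types]
  small <- names(sizes)[sizes < 3L]
  if (length(small)) {
    warning("skipping cell type(s) with < 3 cells: ",
            paste(small, collapse = ", "))
    types <- setdiff(types, small)
  }
  if (length(types) < 2L) stop("need >= 2 cell types with >= 3 cells")
  use <- cells$cell_type %in% types
  norm <- norm[use, , drop = FALSE]
  grp <- factor(cells$cell_type[use], levels = types)
  cr <- .col_ranks(norm)
  genes <- colnames(norm)
  eps <- 1e-9
  n_by <- as.vector(table(grp))
  # per-type sums of de-logged values and detection flags, one pass each
  sum_expm <- rowsum(2^norm - 1, grp)
  sum_det <- rowsum((norm > 0) + 0, grp)
  tot_expm <- colSums(sum_expm); tot_det <- colSums(sum_det)
  n_tot <- sum(n_by)
  out <- vector("list", length(types))
  for (i in seq_along(types)) {
    idx <- grp == types[i]
    p <- .wilcox_genes(cr$R, cr$tie, idx)
    m_in <- sum_expm[i, ] / n_by[i]
    m_out <- (tot_expm - sum_expm[i, ]) / (n_tot - n_by[i])
    out[[i]] <- data.frame(
      cell_type = types[i], gene_id = genes,
      log2fc = log2((m_in + eps) / (m_out + eps)),
      p = p, q = bh_adjust(p),
      pct_in = sum_det[i, ] / n_by[i],
      pct_out = (tot_det - sum_det[i, ]) / (n_tot - n_by[i]),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Pairwise differentially-expressed-gene counts between cell types
#'
#' For every unordered pair of cell types, counts the genes with
#' `q <= max_q` and `|log2FC| >= min_lfc` in the two-group Wilcoxon
#' comparison.  The result is symmetric with a zero diagonal; the scaled
#' variant divides by the matrix maximum (`scale = "max"`, default) or
#' min-max rescales (`scale = "minmax"`).
#'
#' @inheritParams find_signatures
#' @param scale Scaling of the `scaled` component.
#' @return List of class `deg_count_matrix` with `raw` and `scaled`
#'   square matrices over the cell types.
#' @export
pairwise_deg_counts <- function(norm, cells, min_lfc = 1, max_q = 0.05,
                                scale = c("max", "minmax")) {
  scale <- match.arg(scale)
  types <- unique(cells$cell_type)
  sizes <- table(cells$cell_type)[types]
  small <- names(sizes)[sizes < 3L]
  if (length(small)) {
    warning("skipping cell type(s) with < 3 cells: ",
            paste(small, collapse = ", "))
    types <- setdiff(types, small)
  }
  if (length(types) < 2L) stop("need >= 2 cell types with >= 3 cells")
  k <- length(types)
  raw <- matrix(0, k, k, dimnames = list(types, types))
  idx_by_type <- lapply(types, function(t) which(cells$cell_type == t))
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      sub <- c(idx_by_type[[a]], idx_by_type[[b]])
      X <- norm[sub, , drop = FALSE]
      in_idx <- seq_along(sub) <= length(idx_by_type[[a]])
      cr <- .col_ranks(X)
      p <- .wilcox_genes(cr$R, cr$tie, in_idx)
      q <- bh_adjust(p)
      lfc <- .log2fc(X, in_idx)
      raw[a, b] <- raw[b, a] <- sum(q <= max_q & abs(lfc) >= min_lfc)
    }
  }
  scaled <- if (max(raw) > 0) {
    if (scale == "max") raw / max(raw)
    else (raw - min(raw)) / (max(raw) - min(raw))
  } else raw
  structure(list(raw = raw, scaled = scaled, scale = scale),
            class = "deg_count_matrix")
}

#' Concordance of coding and lncRNA DEG-count matrices
#'
#' Spearman correlation between the off-diagonal entries of two
#' [pairwise_deg_counts()] results over the same cell-type ordering, plus
#' a composite matrix (coding counts in the lower triangle, lncRNA counts
#' in the upper) for heat-map display.
#'
#' @param coding,lnc `deg_count_matrix` objects with identical type
#'   orderings (mismatch is a fatal error).
#' @return List with `rho` and `composite` (scaled composite matrix).
#' @export
deg_concordance <- function(coding, lnc) {
  a <- coding$raw; b <- lnc$raw
  if (!identical(dimnames(a), dimnames(b)))
    stop("cell-type orderings of the two DEG matrices differ")
  off <- upper.tri(a)
  rho <- stats::cor(a[off], b[off], method = "spearman")
  comp <- coding$scaled
  comp[upper.tri(comp)] <- lnc$scaled[upper.tri(comp)]
  list(rho = rho, composite = comp)
}
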