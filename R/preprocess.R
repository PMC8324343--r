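#' Filter genes by the fraction of cells expressing them
#'
#' Keeps genes detected (count > 0) in at least
#' \code{min_cell_fraction * n_cells} cells; the default removes genes seen
#' in fewer than 0.1\% of cells. Cell set and gene order are preserved.
#'
#' @param expr cells x genes count matrix.
#' @param min_cell_fraction minimum expressing-cell fraction in [0, 1].
#' @return the filtered matrix.
#' @export
filter_genes <- function(expr, min_cell_fraction = 0.001) {
  expr <- as_expression_matrix(expr)
  min_cell_fraction <- check_prob(min_cell_fraction, "min_cell_fraction")
  n_expressing <- Matrix::colSums(expr > 0)
  keep <- n_expressing >= min_cell_fraction * nrow(expr)
  if (min_cell_fraction > 0) keep <- keep & n_expressing > 0
  if (!any(keep))
    stop_invalid("gene filter removed every gene (min_cell_fraction = ",
                 min_cell_fraction, ")")
  expr[, keep, drop = FALSE]
}

#' Library-size normalization and highly-variable-gene selection
#'
#' Each cell is scaled to a fixed total of \code{scale_total} counts and
#' log-transformed (\code{log1p}). Variable genes are ranked by the variance
#' of their raw counts standardized against a loess mean-variance trend
#' (variance divided by the trend's fit), so highly expressed genes are not
#' trivially selected; with very few genes, or if the trend fit fails, the
#' raw count variance is used. A gene with constant counts has zero
#' variance and is never selected.
#'
#' @param expr cells x genes count matrix (after [filter_genes()]).
#' @param n_hvg number of highly variable genes to report.
#' @param scale_total per-cell total after scaling (default 1e4).
#' @return list with \code{normed} (dense cells x genes log-normalized
#'   matrix), \code{hvg} (character vector, most variable first) and
#'   \code{gene_variance} (standardized variance per gene).
#' @export
normalize_and_select <- function(expr, n_hvg = 2000L, scale_total = 1e4) {
  expr <- as_expression_matrix(expr)
  n_hvg <- check_count(n_hvg, "n_hvg")
  totals <- Matrix::rowSums(expr)
  if (any(totals == 0))
    stop_invalid("cells with zero total counts cannot be normalized")
  normed <- as.matrix(expr / totals * scale_total)
  normed <- log1p(normed)

  dense <- as.matrix(expr)
  mu <- colMeans(dense)
  v <- apply(dense, 2L, stats::var)
  std_var <- v
  pos <- v > 0 & mu > 0
  if (sum(pos) >= 10L) {
    fit <- try(stats::loess(log10(v[pos]) ~ log10(mu[pos]), span = 0.5,
                            degree = 2), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      trend <- 10^stats::predict(fit)
      std_var[pos] <- v[pos] / trend
    }
  }
  std_var[v == 0] <- 0  # constant genes can never be variable

  if (n_hvg > ncol(expr)) {
    warning("n_hvg (", n_hvg, ") exceeds gene count (", ncol(expr),
            "); returning all non-constant genes")
    n_hvg <- ncol(expr)
  }
  ord <- order(-std_var, colnames(expr))
  hvg <- colnames(expr)[ord]
  hvg <- hvg[std_var[match(hvg, colnames(expr))] > 0]
  hvg <- utils::head(hvg, n_hvg)
  list(normed = normed, hvg = hvg, gene_variance = std_var)
}

#' PCA, shared-nearest-neighbor graph, and modularity clustering
#'
#' Standard single-cell recipe: z-score the variable genes, PCA to
#' \code{n_pcs} components, build a k-nearest-neighbor graph in PC space,
#' weight edges by the Jaccard similarity of neighbor sets (SNN), and run
#' Louvain modularity community detection at the given resolution. The
#' first two PCs are returned as a plotting embedding.
#'
#' @param normed dense log-normalized cells x genes matrix.
#' @param n_pcs number of principal components (default 10).
#' @param resolution Louvain resolution parameter (default 0.8).
#' @param seed RNG seed for the community search.
#' @param hvg optional character vector restricting the genes used.
#' @param k_nn neighbors for the SNN graph (default 30, capped at n-1).
#' @return list of class \code{cell_annotation}: \code{cluster} (integer
#'   vector named by cell, ids contiguous from 0), \code{cell_type} (named
#'   character, filled by [annotate_clusters()]), \code{embedding}
#'   (cells x 2 matrix).
#' @export
embed_and_cluster <- function(normed, n_pcs = 10L, resolution = 0.8,
                              seed = 1L, hvg = NULL, k_nn = 30L) {
  stopifnot(is.matrix(normed))
  n_pcs <- check_count(n_pcs, "n_pcs")
  if (!is.null(hvg)) normed <- normed[, intersect(hvg, colnames(normed)), drop = FALSE]
  if (n_pcs >= min(dim(normed)))
    stop_invalid("n_pcs (", n_pcs, ") must be smaller than both matrix dimensions")

  keep <- apply(normed, 2L, stats::sd) > 0
  z <- scale(normed[, keep, drop = FALSE])
  pcs <- stats::prcomp(z, center = FALSE, scale. = FALSE, rank. = n_pcs)$x

  n <- nrow(pcs)
  k <- min(k_nn, n - 1L)
  d <- as.matrix(stats::dist(pcs))
  nn <- t(apply(d, 1L, function(row) order(row)[2:(k + 1L)]))

  # SNN: Jaccard overlap of kNN sets (self included, as is conventional);
  # only pairs that are neighbors in at least one direction get an edge
  sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  rnn <- split(rep(seq_len(n), times = k), as.vector(nn))
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cand <- unique(c(nn[i, ], rnn[[as.character(i)]]))
    for (j in cand) {
      if (j <= i) next
      ov <- length(intersect(sets[[i]], sets[[j]]))
      jac <- ov / (2L * (k + 1L) - ov)
      adj[i, j] <- adj[j, i] <- jac
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  cluster <- as.integer(igraph::membership(comm)) - 1L
  # relabel so cluster ids are contiguous from 0 in order of first appearance
  cluster <- match(cluster, unique(cluster)) - 1L
  names(cluster) <- rownames(normed)

  embedding <- pcs[, 1:2, drop = FALSE]
  colnames(embedding) <- c("dim1", "dim2")
  structure(list(cluster = cluster,
                 cell_type = stats::setNames(rep("unassigned",
                                                 length(unique(cluster))),
                                             sort(unique(cluster))),
                 embedding = embedding),
            class = "cell_annotation")
}

#' @export
print.cell_annotation <- function(x, ...) {
  cat("cell_annotation:", length(x$cluster), "cells,",
      length(unique(x$cluster)), "clusters\n")
  tab <- table(x$cluster)
  types <- x$cell_type[as.character(names(tab))]
  for (cl in names(tab))
    cat("  cluster ", cl, ": ", tab[[cl]], " cells (", types[[cl]], ")\n", sep = "")
  invisible(x)
}

#' One-vs-rest Wilcoxon marker detection per cluster
#'
#' For every cluster and gene, a two-sided Wilcoxon rank-sum test of cells
#' in the cluster against all other cells, with Benjamini-Hochberg
#' adjustment across genes within each cluster. The log fold-change is
#' \code{log2((mean_in + eps) / (mean_out + eps))} on the de-logged
#' normalized scale (eps = 1).
#'
#' @param normed dense log-normalized cells x genes matrix.
#' @param annotation \code{cell_annotation} with clusters for every row.
#' @param min_logfc minimum log2 fold-change to report (default 0.25).
#' @param alpha maximum BH-adjusted p-value to report (default 0.05).
#' @return data.frame (cluster, gene, logfc, p, p_adj) sorted by p within
#'   cluster; clusters with fewer than 3 cells are skipped with a warning.
#' @details With small groups the p-value is the exact two-sided
#'   rank-sum permutation probability (valid under ties, where the
#'   classical exact distribution does not apply); larger groups use
#'   \code{stats::wilcox.test}'s tie-corrected normal approximation.
#' @export
find_markers <- function(normed, annotation, min_logfc = 0.25, alpha = 0.05) {
  stopifnot(is.matrix(normed), inherits(annotation, "cell_annotation"))
  cluster <- annotation$cluster[rownames(normed)]
  if (anyNA(cluster)) stop_invalid("annotation does not cover every cell")
  ids <- sort(unique(cluster))
  if (length(ids) < 2L) stop_invalid("marker detection needs >= 2 clusters")

  out <- list()
  for (cl in ids) {
    in_cl <- cluster == cl
    if (sum(in_cl) < 3L) {
      warning("cluster ", cl, " has fewer than 3 cells; skipped")
      next
    }
    p <- apply(normed, 2L, function(g) wilcox_p(g[in_cl], g[!in_cl]))
    p[is.na(p)] <- 1  # constant genes
    mean_in <- colMeans(expm1(normed[in_cl, , drop = FALSE]))
    mean_out <- colMeans(expm1(normed[!in_cl, , drop = FALSE]))
    logfc <- log2((mean_in + 1) / (mean_out + 1))
    p_adj <- stats::p.adjust(p, method = "BH")
    df <- data.frame(cluster = cl, gene = colnames(normed),
                     logfc = logfc, p = p, p_adj = p_adj,
                     row.names = NULL)
    df <- df[df$logfc >= min_logfc & df$p_adj <= alpha, , drop = FALSE]
    out[[as.character(cl)]] <- df[order(df$p, df$gene), , drop = FALSE]
  }
  res <- do.call(rbind, c(list(data.frame(cluster = integer(), gene = character(),
                                          logfc = numeric(), p = numeric(),
                                          p_adj = numeric())), out))
  rownames(res) <- NULL
  res
}

# two-sided rank-sum p: exact permutation enumeration for small groups
# (handles ties exactly), tie-corrected normal approximation otherwise
wilcox_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  if (choose(n, n1) <= 200) {
    r <- rank(c(x, y))
    obs <- sum(r[seq_len(n1)])
    sums <- utils::combn(n, n1, function(idx) sum(r[idx]))
    mu <- mean(sums)
    mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
  } else {
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }
}

#' Label clusters from a reference marker table
#'
#' Scores each cluster against each reference cell type as the mean z-scored
#' expression of that type's reference markers across the cluster's cells,
#' and assigns the top-scoring type. Clusters whose best score does not
#' exceed \code{score_floor}, or where two types tie exactly, are labeled
#' \code{"unassigned"}.
#'
#' @param normed dense log-normalized cells x genes matrix.
#' @param annotation \code{cell_annotation} from [embed_and_cluster()].
#' @param reference data.frame with columns \code{cell_type} and \code{gene},
#'   or a path to such a TSV.
#' @param score_floor minimum winning score for assignment (default 0).
#' @return the annotation with its \code{cell_type} map filled in.
#' @export
annotate_clusters <- function(normed, annotation, reference, score_floor = 0) {
  stopifnot(is.matrix(normed), inherits(annotation, "cell_annotation"))
  if (is.character(reference) && length(reference) == 1L)
    reference <- read.delim(reference, stringsAsFactors = FALSE)
  if (!all(c("cell_type", "gene") %in% names(reference)) || nrow(reference) == 0L)
    stop_invalid("reference must be a non-empty table with columns cell_type, gene")

  missing <- setdiff(reference$gene, colnames(normed))
  if (length(missing))
    warning("reference genes absent from matrix, ignored: ",
            paste(missing, collapse = ", "))
  reference <- reference[reference$gene %in% colnames(normed), , drop = FALSE]
  types <- unique(reference$cell_type)
  usable <- vapply(types, function(ty)
    sum(reference$cell_type == ty) > 0L, logical(1))
  if (!all(usable))
    warning("reference types with no usable markers: ",
            paste(types[!usable], collapse = ", "))
  types <- types[usable]
  if (length(types) == 0L) stop_invalid("no usable reference markers")

  z <- scale(normed)
  z[, attr(z, "scaled:scale") == 0] <- 0
  cluster <- annotation$cluster[rownames(normed)]
  ids <- sort(unique(cluster))
  labels <- stats::setNames(rep("unassigned", length(ids)), ids)
  for (cl in ids) {
    cells <- cluster == cl
    scores <- vapply(types, function(ty) {
      g <- reference$gene[reference$cell_type == ty]
      mean(z[cells, g, drop = FALSE])
    }, numeric(1))
    best <- max(scores)
    if (best > score_floor && sum(scores == best) == 1L)
      labels[as.character(cl)] <- types[which.max(scores)]
  }
  annotation$cell_type <- labels
  annotation
}

#' Per-cell type labels implied by an annotated clustering
#' @param annotation an annotated \code{cell_annotation}.
#' @return character vector of cell-type labels, named by cell.
#' @export
cell_labels <- function(annotation) {
  stopifnot(inherits(annotation, "cell_annotation"))
  stats::setNames(annotation$cell_type[as.character(annotation$cluster)],
                  names(annotation$cluster))
}
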