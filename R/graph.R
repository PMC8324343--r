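#' Cell-type similarity graph from regulon activity
#'
#' Each cell type's profile is its per-type mean activity over regulons.
#' Types are compared by Spearman correlation (average ranks for ties) and
#' linked when rho strictly exceeds the threshold. Types with fewer than 2
#' cells are excluded with a warning.
#'
#' @param ras cells x regulons activity matrix.
#' @param labels cell-type label per cell.
#' @param threshold link threshold on Spearman rho (default 0.8, strict).
#' @return list of class \code{celltype_graph}: \code{nodes}, \code{edges}
#'   (data.frame type_a, type_b, rho, linked for every pair),
#'   \code{profiles} (types x regulons matrix).
#' @export
celltype_graph <- function(ras, labels, threshold = 0.8) {
  stopifnot(is.matrix(ras), length(labels) == nrow(ras))
  labels <- as.character(labels)
  types <- unique(labels)
  small <- types[table(factor(labels, types))[types] < 2L]
  if (length(small)) {
    warning("cell types with < 2 cells excluded: ",
            paste(small, collapse = ", "))
    types <- setdiff(types, small)
  }
  if (length(types) < 2L) stop_invalid("need >= 2 usable cell types")

  profiles <- t(vapply(types, function(ct)
    colMeans(ras[labels == ct, , drop = FALSE]), numeric(ncol(ras))))
  rownames(profiles) <- types

  pairs <- utils::combn(types, 2L)
  edges <- data.frame(type_a = pairs[1L, ], type_b = pairs[2L, ],
                      rho = NA_real_, linked = FALSE)
  for (i in seq_len(nrow(edges))) {
    rho <- suppressWarnings(stats::cor(profiles[edges$type_a[i], ],
                                       profiles[edges$type_b[i], ],
                                       method = "spearman"))
    edges$rho[i] <- if (is.finite(rho)) rho else 0
    edges$linked[i] <- edges$rho[i] > threshold
  }
  structure(list(nodes = types, edges = edges, profiles = profiles,
                 threshold = threshold),
            class = "celltype_graph")
}

#' @export
print.celltype_graph <- function(x, ...) {
  cat("celltype_graph:", length(x$nodes), "types,",
      sum(x$edges$linked), "links (rho >", x$threshold, ")\n")
  invisible(x)
}

#' Markov Clustering (MCL) of a weighted undirected graph
#'
#' Classic MCL: self-loops are added, the adjacency is column-normalized to
#' a stochastic matrix, and expansion (matrix squaring) alternates with
#' inflation (elementwise power then renormalization) until the matrix
#' stops changing. Clusters are read off as the connected components of the
#' converged matrix's support. Deterministic; no randomness is involved.
#'
#' @param graph a \code{celltype_graph}, or a symmetric non-negative
#'   adjacency matrix with dimnames.
#' @param inflation inflation exponent (> 1; default 2).
#' @param max_iter iteration cap (default 100).
#' @param tol convergence threshold on the max absolute change (1e-8).
#' @param prune entries below this are zeroed each iteration (1e-6).
#' @param self_loop weight of the added self-loops (default 1).
#' @return list of clusters (character vectors of node names) partitioning
#'   the node set, ordered by decreasing size then first member.
#' @export
mcl_cluster <- function(graph, inflation = 2, max_iter = 100L, tol = 1e-8,
                        prune = 1e-6, self_loop = 1) {
  if (inherits(graph, "celltype_graph")) {
    nodes <- graph$nodes
    adj <- matrix(0, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    linked <- graph$edges[graph$edges$linked, , drop = FALSE]
    for (i in seq_len(nrow(linked))) {
      w <- max(linked$rho[i], 0)
      adj[linked$type_a[i], linked$type_b[i]] <- w
      adj[linked$type_b[i], linked$type_a[i]] <- w
    }
  } else {
    adj <- as.matrix(graph)
  }
  stopifnot(nrow(adj) == ncol(adj))
  if (nrow(adj) == 0L) stop_invalid("empty graph")
  if (!is.numeric(inflation) || inflation <= 1)
    stop_invalid("`inflation` must be > 1")
  if (is.null(rownames(adj)))
    dimnames(adj) <- list(seq_len(nrow(adj)), seq_len(nrow(adj)))
  if (max(abs(adj - t(adj))) > 1e-12 || any(adj < 0))
    stop_invalid("adjacency must be symmetric and non-negative")

  m <- adj
  diag(m) <- diag(m) + self_loop
  normalize <- function(x) sweep(x, 2L, colSums(x), "/")
  m <- normalize(m)
  for (it in seq_len(max_iter)) {
    prev <- m
    m <- m %*% m              # expansion
    m <- m ^ inflation        # inflation
    m[m < prune] <- 0
    m <- normalize(m)
    if (max(abs(m - prev)) < tol) break
  }

  support <- (m > prune) | (t(m) > prune)
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  clusters <- split(rownames(adj), comp)
  clusters <- lapply(clusters, sort)
  sizes <- vapply(clusters, length, integer(1))
  first <- vapply(clusters, `[`, character(1), 1L)
  clusters <- clusters[order(-sizes, first)]
  names(clusters) <- NULL
  clusters
}
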