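#' Per-cell regulon activity scores (rank-based recovery AUC)
#'
#' For each cell, genes are ranked by descending expression; ties are broken
#' by one fixed, seeded permutation of the gene order so results are
#' bit-reproducible. The regulon's score is the area under its step recovery
#' curve within the top \code{ceiling(top_fraction * n_genes)} ranks,
#' normalized by the maximal possible area (all regulon genes at the very
#' top), so scores lie in [0, 1].
#'
#' @param expr cells x genes matrix; raw counts or normalized values — the
#'   statistic is rank-based and invariant to monotone per-cell transforms.
#' @param regulons list of \code{regulon} objects (or a
#'   \code{ground_truth_network} via [truth_regulons()]).
#' @param top_fraction fraction of top-ranked genes scored (default 0.05).
#' @param seed seed for the tie-breaking permutation.
#' @return numeric matrix, cells x regulons, entries in [0, 1]; regulon
#'   columns named by TF.
#' @export
score_regulon_activity <- function(expr, regulons, top_fraction = 0.05,
                                   seed = 1L) {
  if (inherits(regulons, "ground_truth_network"))
    regulons <- truth_regulons(regulons)
  if (methods::is(expr, "sparseMatrix")) expr <- as.matrix(expr)
  stopifnot(is.matrix(expr), length(regulons) >= 1L)
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction >= 1)
    stop_invalid("`top_fraction` must lie strictly between 0 and 1")

  n_genes <- ncol(expr)
  k <- as.integer(ceiling(top_fraction * n_genes))
  set.seed(seed)
  tiebreak <- sample.int(n_genes)

  # rank position of every gene in every cell (1 = most expressed)
  pos <- matrix(0L, nrow = nrow(expr), ncol = n_genes, dimnames = dimnames(expr))
  for (i in seq_len(nrow(expr))) {
    ord <- order(-expr[i, ], tiebreak)
    pos[i, ord] <- seq_len(n_genes)
  }

  names(regulons) <- vapply(regulons, `[[`, character(1), "tf")
  scores <- matrix(0, nrow = nrow(expr), ncol = length(regulons),
                   dimnames = list(rownames(expr), names(regulons)))
  for (r in names(regulons)) {
    genes <- intersect(regulons[[r]]$targets, colnames(expr))
    dropped <- setdiff(regulons[[r]]$targets, genes)
    if (length(dropped))
      warning("regulon ", r, ": ", length(dropped),
              " gene(s) absent from matrix, dropped")
    if (length(genes) == 0L) {
      warning("regulon ", r, " has no genes in the matrix; scores set to 0")
      next
    }
    m <- min(length(genes), k)
    max_area <- sum(k - seq_len(m) + 1L)
    p <- pos[, genes, drop = FALSE]
    inside <- p <= k
    raw <- rowSums((k - p + 1L) * inside)
    scores[, r] <- raw / max_area
  }
  scores
}

#' Pooled-cell (Avg20) activity scoring with a noise comparison
#'
#' Within each cell type, cells are partitioned at random into disjoint
#' pools of \code{pool_size}; each pool's expression profile is the mean of
#' its members' raw counts, and regulon activity is re-scored on the pooled
#' profiles. The within-type coefficient of variation (CV) of pooled scores
#' is compared against the CV of single-cell scores by a two-sided Welch
#' t-test per regulon (pooled CVs across types and repeats versus
#' single-cell CVs across types). The whole procedure is repeated
#' \code{n_repeats} times with distinct sub-seeds to expose sampling
#' variability.
#'
#' @param expr cells x genes count matrix.
#' @param labels cell-type label per cell (length \code{nrow(expr)}).
#' @param regulons regulon list (or \code{ground_truth_network}).
#' @param pool_size cells per pool (default 20).
#' @param n_repeats number of random partitions (default 3).
#' @param top_fraction,seed passed to [score_regulon_activity()].
#' @return list of class \code{pooling_report}: \code{pool_size},
#'   \code{n_repeats}, \code{pooled_ras} (list of per-repeat pooled activity
#'   matrices with pool labels as attribute), \code{cv} (data.frame of
#'   within-type CVs: regulon, cell_type, repeat_, pooled_cv, single_cv),
#'   \code{tests} (per-regulon Welch statistic and p).
#' @export
pool_and_compare <- function(expr, labels, regulons, pool_size = 20L,
                             n_repeats = 3L, top_fraction = 0.05, seed = 1L) {
  if (inherits(regulons, "ground_truth_network"))
    regulons <- truth_regulons(regulons)
  expr <- as_expression_matrix(expr)
  stopifnot(length(labels) == nrow(expr))
  pool_size <- check_count(pool_size, "pool_size", min = 2L)
  n_repeats <- check_count(n_repeats, "n_repeats")

  types <- unique(as.character(labels))
  small <- types[table(factor(labels, types))[types] < pool_size]
  if (length(small)) {
    warning("cell types with fewer than pool_size cells skipped: ",
            paste(small, collapse = ", "))
    types <- setdiff(types, small)
  }
  if (length(types) == 0L) stop_invalid("no cell type has >= pool_size cells")

  sc_ras <- score_regulon_activity(expr, regulons,
                                   top_fraction = top_fraction, seed = seed)
  reg_names <- colnames(sc_ras)
  single_cv <- sapply(types, function(ct)
    apply(sc_ras[labels == ct, , drop = FALSE], 2L, cv))
  # regulons x types matrix of single-cell CVs
  single_cv <- matrix(single_cv, nrow = length(reg_names),
                      dimnames = list(reg_names, types))

  pooled_ras <- vector("list", n_repeats)
  cv_rows <- list()
  for (r in seq_len(n_repeats)) {
    set.seed(derive_seed(seed, 7000L + r))
    pools <- list()
    pool_type <- character()
    for (ct in types) {
      cells <- sample(which(labels == ct))
      n_pools <- floor(length(cells) / pool_size)
      for (p in seq_len(n_pools)) {
        pools[[length(pools) + 1L]] <-
          cells[((p - 1L) * pool_size + 1L):(p * pool_size)]
        pool_type <- c(pool_type, ct)
      }
    }
    pooled <- t(vapply(pools, function(idx)
      Matrix::colMeans(expr[idx, , drop = FALSE]), numeric(ncol(expr))))
    rownames(pooled) <- sprintf("pool_%03d", seq_along(pools))
    colnames(pooled) <- colnames(expr)
    ras_p <- score_regulon_activity(pooled, regulons,
                                    top_fraction = top_fraction, seed = seed)
    attr(ras_p, "pool_type") <- pool_type
    pooled_ras[[r]] <- ras_p
    for (ct in types) {
      sub <- ras_p[pool_type == ct, , drop = FALSE]
      cv_rows[[length(cv_rows) + 1L]] <- data.frame(
        regulon = reg_names, cell_type = ct, repeat_ = r,
        pooled_cv = apply(sub, 2L, cv),
        single_cv = single_cv[, ct], row.names = NULL)
    }
  }
  cv_df <- do.call(rbind, cv_rows)

  tests <- do.call(rbind, lapply(reg_names, function(rn) {
    pc <- cv_df$pooled_cv[cv_df$regulon == rn]
    sc <- single_cv[rn, ]
    pc <- pc[is.finite(pc)]; sc <- sc[is.finite(sc)]
    if (length(pc) >= 2L && length(sc) >= 2L &&
        (stats::sd(pc) > 0 || stats::sd(sc) > 0)) {
      tt <- stats::t.test(pc, sc)
      data.frame(regulon = rn, statistic = unname(tt$statistic),
                 p = tt$p.value, mean_pooled_cv = mean(pc),
                 mean_single_cv = mean(sc), row.names = NULL)
    } else {
      data.frame(regulon = rn, statistic = NA_real_, p = NA_real_,
                 mean_pooled_cv = mean(pc), mean_single_cv = mean(sc),
                 row.names = NULL)
    }
  }))

  structure(list(pool_size = pool_size, n_repeats = n_repeats,
                 single_cell_ras = sc_ras, pooled_ras = pooled_ras,
                 cv = cv_df, tests = tests),
            class = "pooling_report")
}

#' @export
print.pooling_report <- function(x, ...) {
  cat("pooling_report: pools of", x$pool_size, "cells,", x$n_repeats,
      "repeats,", nrow(x$tests), "regulons\n")
  better <- sum(x$tests$mean_pooled_cv < x$tests$mean_single_cv, na.rm = TRUE)
  cat("  regulons with lower pooled CV:", better, "/", nrow(x$tests), "\n")
  invisible(x)
}
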