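#' Infer TF-to-target importances from expression
#'
#' For every non-TF gene, scores how well each transcription factor's
#' expression predicts it. In \code{"tree"} mode a seeded random-forest
#' regression (100 trees, depth-limited) is fit per target and the impurity
#' importances of the TF features are reported; in \code{"correlation"} mode
#' the importance is the absolute Spearman correlation. Self-edges never
#' appear.
#'
#' @param normed dense log-normalized cells x genes matrix.
#' @param tf_list character vector of TF symbols, all present in the matrix.
#' @param method \code{"tree"} (default) or \code{"correlation"}.
#' @param seed RNG seed for tree mode (correlation mode is deterministic).
#' @param num_trees,max_depth tree-ensemble controls.
#' @return data.frame (tf, target, importance) with finite non-negative
#'   importances and at most one row per pair.
#' @export
infer_importances <- function(normed, tf_list, method = c("tree", "correlation"),
                              seed = 1L, num_trees = 100L, max_depth = 5L) {
  stopifnot(is.matrix(normed))
  method <- match.arg(method)
  if (length(tf_list) == 0L) stop_invalid("`tf_list` is empty")
  missing <- setdiff(tf_list, colnames(normed))
  if (length(missing))
    stop_invalid("TFs absent from matrix: ", paste(missing, collapse = ", "))
  targets <- setdiff(colnames(normed), tf_list)
  if (length(targets) == 0L) stop_invalid("no non-TF target genes in matrix")

  tf_expr <- normed[, tf_list, drop = FALSE]
  if (method == "correlation") {
    rho <- suppressWarnings(
      stats::cor(tf_expr, normed[, targets, drop = FALSE], method = "spearman"))
    rho[!is.finite(rho)] <- 0
    out <- data.frame(tf = rep(tf_list, times = length(targets)),
                      target = rep(targets, each = length(tf_list)),
                      importance = abs(as.vector(rho)))
  } else {
    df <- as.data.frame(tf_expr)
    names(df) <- make.names(tf_list)
    imp <- vapply(seq_along(targets), function(ti) {
      fit <- ranger::ranger(x = df, y = normed[, targets[ti]],
                            num.trees = num_trees, max.depth = max_depth,
                            importance = "impurity", num.threads = 1L,
                            seed = derive_seed(seed, ti))
      pmax(fit$variable.importance, 0)
    }, numeric(length(tf_list)))
    out <- data.frame(tf = rep(tf_list, times = length(targets)),
                      target = rep(targets, each = length(tf_list)),
                      importance = as.vector(imp))
  }
  rownames(out) <- NULL
  out
}

#' Assemble candidate TF modules from an importance edge table
#'
#' An edge survives if any enabled rule keeps it: \code{top_k} retains each
#' target's k strongest TF edges; \code{quantile} retains edges whose
#' importance strictly exceeds the given quantile of all importances.
#' Surviving edges are grouped by TF.
#'
#' @param edges data.frame (tf, target, importance) from
#'   [infer_importances()].
#' @param top_k per-target edge count to keep, or NULL to disable.
#' @param quantile importance quantile in [0, 1], or NULL to disable.
#' @return named list mapping TF to its candidate target genes (sorted).
#' @export
build_candidate_modules <- function(edges, top_k = 10L, quantile = 0.9) {
  stopifnot(is.data.frame(edges),
            all(c("tf", "target", "importance") %in% names(edges)))
  if (nrow(edges) == 0L) stop_invalid("empty edge table")
  if (is.null(top_k) && is.null(quantile))
    stop_invalid("at least one rule (top_k, quantile) must be enabled")

  keep <- rep(FALSE, nrow(edges))
  if (!is.null(top_k)) {
    top_k <- check_count(top_k, "top_k")
    ord <- order(edges$target, -edges$importance, edges$tf)
    rank_in_target <- stats::ave(seq_along(ord), edges$target[ord],
                                 FUN = seq_along)
    keep[ord] <- keep[ord] | rank_in_target <= top_k
  }
  if (!is.null(quantile)) {
    q <- check_prob(quantile, "quantile")
    thr <- stats::quantile(edges$importance, q, names = FALSE)
    keep <- keep | edges$importance > thr
  }
  kept <- edges[keep, , drop = FALSE]
  if (nrow(kept) == 0L)
    stop_invalid("candidate rules retained no edges; relax top_k/quantile")
  lapply(split(kept$target, kept$tf), function(x) sort(unique(x)))
}

#' Prune candidate modules to positive regulons
#'
#' A candidate target is kept only if (a) the pair is allowed by the prior
#' mask, when one is given, and (b) its Pearson correlation with the TF is
#' strictly positive — only positive (activating) regulation is modeled.
#' Regulons with fewer than \code{min_targets} surviving targets are
#' dropped. Output is sorted by TF symbol.
#'
#' @param candidates named list TF -> candidate targets from
#'   [build_candidate_modules()].
#' @param normed dense log-normalized cells x genes matrix.
#' @param prior optional prior mask: data.frame with columns \code{tf} and
#'   \code{target} (or path to such a TSV); NULL disables mask pruning.
#' @param min_targets minimum regulon size (default 3).
#' @param edges optional importance table to carry through as provenance.
#' @return list of \code{regulon} objects (possibly empty), each with
#'   fields \code{tf}, \code{targets}, \code{importance}, \code{correlation}.
#' @export
prune_to_regulons <- function(candidates, normed, prior = NULL,
                              min_targets = 3L, edges = NULL) {
  if (length(candidates) == 0L) stop_invalid("no candidate modules")
  stopifnot(is.matrix(normed))
  min_targets <- check_count(min_targets, "min_targets")
  if (is.character(prior) && length(prior) == 1L)
    prior <- read.delim(prior, stringsAsFactors = FALSE)
  allowed <- NULL
  if (!is.null(prior)) {
    stopifnot(all(c("tf", "target") %in% names(prior)))
    allowed <- paste(prior$tf, prior$target, sep = "\r")
  }

  regulons <- list()
  for (tf in sort(names(candidates))) {
    targets <- setdiff(candidates[[tf]], tf)
    if (!is.null(allowed))
      targets <- targets[paste(tf, targets, sep = "\r") %in% allowed]
    targets <- intersect(targets, colnames(normed))
    if (length(targets) == 0L) next
    rho <- suppressWarnings(
      stats::cor(normed[, tf], normed[, targets, drop = FALSE]))[1L, ]
    rho[!is.finite(rho)] <- 0
    targets <- targets[rho > 0]
    if (length(targets) < min_targets) next
    imp <- stats::setNames(rep(NA_real_, length(targets)), targets)
    if (!is.null(edges)) {
      m <- edges[edges$tf == tf & edges$target %in% targets, , drop = FALSE]
      imp[m$target] <- m$importance
    }
    regulons[[tf]] <- structure(
      list(tf = tf, targets = sort(targets),
           importance = imp[sort(targets)],
           correlation = rho[sort(targets)]),
      class = "regulon")
  }
  if (length(regulons) == 0L)
    message("pruning produced zero regulons")
  regulons
}

#' @export
print.regulon <- function(x, ...) {
  cat("regulon ", x$tf, ": ", length(x$targets), " targets (",
      paste(utils::head(x$targets, 5L), collapse = ", "),
      if (length(x$targets) > 5L) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' Flatten a regulon list to an edge table / write it as TSV
#'
#' @param regulons list of \code{regulon} objects.
#' @return data.frame (tf, target, importance, correlation).
#' @export
regulons_to_table <- function(regulons) {
  do.call(rbind, c(list(data.frame(tf = character(), target = character(),
                                   importance = numeric(),
                                   correlation = numeric())),
                   lapply(regulons, function(r)
                     data.frame(tf = r$tf, target = r$targets,
                                importance = unname(r$importance),
                                correlation = unname(r$correlation),
                                row.names = NULL))))
}

#' @rdname regulons_to_table
#' @param path TSV file to write.
#' @export
write_regulons <- function(regulons, path) {
  write.table(regulons_to_table(regulons), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a regulon table written by [write_regulons()]
#' @param path TSV with columns tf, target (importance/correlation optional).
#' @return list of \code{regulon} objects.
#' @export
read_regulons <- function(path) {
  if (!file.exists(path)) stop_io("missing regulon file '", path, "'")
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("tf", "target") %in% names(df)))
  lapply(split(df, df$tf), function(d) {
    ord <- order(d$target)
    structure(list(
      tf = d$tf[1L], targets = d$target[ord],
      importance = stats::setNames(
        if ("importance" %in% names(d)) d$importance[ord]
        else rep(NA_real_, nrow(d)), d$target[ord]),
      correlation = stats::setNames(
        if ("correlation" %in% names(d)) d$correlation[ord]
        else rep(NA_real_, nrow(d)), d$target[ord])),
      class = "regulon")
  })
}

#' Regulon lists from a ground-truth network
#'
#' Converts planted truth into the same \code{regulon} structure the
#' inference path produces, for recovery scoring and truth-driven activity.
#'
#' @param gt a \code{ground_truth_network}.
#' @return list of \code{regulon} objects, one per TF.
#' @export
truth_regulons <- function(gt) {
  stopifnot(inherits(gt, "ground_truth_network"))
  lapply(stats::setNames(gt$tfs, gt$tfs), function(tf) {
    tg <- sort(gt$targets[[tf]])
    structure(list(tf = tf, targets = tg,
                   importance = stats::setNames(rep(NA_real_, length(tg)), tg),
                   correlation = stats::setNames(rep(NA_real_, length(tg)), tg)),
              class = "regulon")
  })
}

#' Edge-level precision and recall of inferred regulons against truth
#'
#' @param regulons inferred regulon list.
#' @param gt a \code{ground_truth_network}.
#' @return list with \code{precision}, \code{recall}, \code{n_inferred},
#'   \code{n_true}.
#' @export
edge_recovery <- function(regulons, gt) {
  inf <- regulons_to_table(regulons)
  tru <- network_edges(gt)
  inf_keys <- paste(inf$tf, inf$target, sep = "\r")
  tru_keys <- paste(tru$tf, tru$target, sep = "\r")
  tp <- sum(inf_keys %in% tru_keys)
  list(precision = if (length(inf_keys)) tp / length(inf_keys) else NA_real_,
       recall = if (length(tru_keys)) tp / length(tru_keys) else NA_real_,
       n_inferred = length(inf_keys), n_true = length(tru_keys))
}
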