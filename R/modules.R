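#' Pearson correlation between regulon activity profiles
#'
#' @param ras cells x regulons activity matrix (>= 2 regulons, >= 3 cells).
#' @return symmetric regulons x regulons Pearson matrix with unit diagonal;
#'   zero-variance regulon columns correlate 0 with everything (warning).
#' @export
regulon_correlation <- function(ras) {
  stopifnot(is.matrix(ras))
  if (ncol(ras) < 2L) stop_invalid("need >= 2 regulons")
  if (nrow(ras) < 3L) stop_invalid("need >= 3 cells")
  flat <- apply(ras, 2L, stats::sd) == 0
  if (any(flat))
    warning("zero-variance regulons set to correlation 0: ",
            paste(colnames(ras)[flat], collapse = ", "))
  pcc <- suppressWarnings(stats::cor(ras))
  pcc[!is.finite(pcc)] <- 0
  diag(pcc) <- 1
  pcc
}

#' Connection specificity index of a correlation matrix
#'
#' CSI(A, B) is the fraction of all N regulons C whose correlation with
#' both A and B lies strictly below pcc(A, B) - offset. A pair is
#' "specifically" connected when most other regulons correlate with both
#' members more weakly than the members do with each other; this sharpens
#' block structure relative to the raw correlations. The diagonal is set
#' to 1.
#'
#' @param pcc square symmetric correlation matrix.
#' @param offset subtracted from the pair's correlation before the strict
#'   comparison (default 0.05).
#' @return symmetric matrix with entries in [0, 1], unit diagonal.
#' @export
compute_csi <- function(pcc, offset = 0.05) {
  stopifnot(is.matrix(pcc), nrow(pcc) == ncol(pcc))
  if (max(abs(pcc - t(pcc))) > 1e-12)
    stop_invalid("correlation matrix must be symmetric")
  n <- nrow(pcc)
  csi <- matrix(0, n, n, dimnames = dimnames(pcc))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      thr <- pcc[a, b] - offset
      csi[a, b] <- sum(pcc[a, ] < thr & pcc[b, ] < thr) / n
    }
  }
  diag(csi) <- 1
  csi
}

#' Detect regulon modules by hierarchical clustering of the CSI matrix
#'
#' Average-linkage hierarchical clustering on the distance 1 - CSI, cut at
#' \code{k} modules. Modules are numbered M1..Mk by decreasing size, ties
#' by the lexically smallest member, so the labeling is deterministic and
#' independent of input order.
#'
#' @param csi symmetric CSI matrix from [compute_csi()].
#' @param k number of modules (default 4).
#' @return named list M1..Mk of member regulon vectors (sorted); together
#'   they partition the regulon set.
#' @export
detect_modules <- function(csi, k = 4L) {
  stopifnot(is.matrix(csi), nrow(csi) == ncol(csi))
  k <- check_count(k, "k")
  if (k > nrow(csi)) stop_invalid("k (", k, ") exceeds regulon count")
  ord <- order(rownames(csi))
  csi <- csi[ord, ord]
  hc <- stats::hclust(stats::as.dist(1 - csi), method = "average")
  cut <- stats::cutree(hc, k = k)
  groups <- split(names(cut), cut)
  groups <- lapply(groups, sort)
  sizes <- vapply(groups, length, integer(1))
  first <- vapply(groups, `[`, character(1), 1L)
  groups <- groups[order(-sizes, first)]
  names(groups) <- sprintf("M%d", seq_along(groups))
  groups
}

#' Mean module activity per cell type
#'
#' The activity of module M in type c is the mean activity score over M's
#' member regulons and all cells of type c. The member with the highest
#' per-type mean activity is reported as the module's top regulon in that
#' type.
#'
#' @param ras cells x regulons activity matrix.
#' @param labels cell-type label per cell.
#' @param modules named list of member regulons from [detect_modules()].
#' @return list with \code{activity} (modules x types matrix) and
#'   \code{top_member} (modules x types character matrix).
#' @export
module_activity_by_type <- function(ras, labels, modules) {
  stopifnot(is.matrix(ras), length(labels) == nrow(ras))
  if (any(vapply(modules, length, integer(1)) == 0L))
    stop_invalid("empty module")
  members <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(members) || !setequal(members, colnames(ras)))
    stop_invalid("modules must partition the regulon set of `ras`")
  types <- unique(as.character(labels))
  act <- matrix(0, length(modules), length(types),
                dimnames = list(names(modules), types))
  top <- matrix(NA_character_, length(modules), length(types),
                dimnames = list(names(modules), types))
  for (m in names(modules)) {
    for (ct in types) {
      sub <- ras[labels == ct, modules[[m]], drop = FALSE]
      act[m, ct] <- mean(sub)
      per_reg <- colMeans(sub)
      top[m, ct] <- modules[[m]][order(-per_reg, modules[[m]])[1L]]
    }
  }
  list(activity = act, top_member = top)
}
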