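#' Jensen-Shannon divergence between two probability vectors (base 2)
#'
#' With base-2 logarithms the divergence lies in [0, 1]: 0 for identical
#' distributions, 1 for disjoint supports. The convention 0 log 0 = 0 is
#' applied throughout.
#'
#' @param p,q non-negative vectors of equal length summing to 1.
#' @return a single number in [0, 1].
#' @export
js_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  (kl(p) + kl(q)) / 2
}

#' Regulon specificity scores from Jensen-Shannon divergence
#'
#' For regulon R and cell type c, the regulon's activity vector over cells
#' is normalized to a probability distribution P_R, the type's cell
#' indicator to P_c, and RSS(R, c) = 1 - sqrt(JSD(P_R, P_c)) with base-2
#' JSD. RSS is 1 exactly when the regulon is uniformly active on the
#' type's cells and silent elsewhere, and 0 when its support is disjoint
#' from the type.
#'
#' @param ras cells x regulons activity matrix from
#'   [score_regulon_activity()].
#' @param labels cell-type label per cell; every cell must be labeled.
#' @return regulons x cell-types matrix with entries in [0, 1]; all-zero
#'   activity columns give an RSS row of zeros with a warning.
#' @export
compute_rss <- function(ras, labels) {
  stopifnot(is.matrix(ras))
  labels <- as.character(labels)
  if (length(labels) != nrow(ras) || anyNA(labels))
    stop_invalid("every cell needs a non-missing label")
  if (any(ras < 0)) stop_invalid("activity scores must be non-negative")
  types <- unique(labels)
  rss <- matrix(0, nrow = ncol(ras), ncol = length(types),
                dimnames = list(colnames(ras), types))
  for (r in seq_len(ncol(ras))) {
    tot <- sum(ras[, r])
    if (tot == 0) {
      warning("regulon ", colnames(ras)[r],
              " has all-zero activity; RSS set to 0")
      next
    }
    p <- ras[, r] / tot
    for (ct in types) {
      q <- as.numeric(labels == ct)
      q <- q / sum(q)
      rss[r, ct] <- 1 - sqrt(js_divergence(p, q))
    }
  }
  rss
}

#' Top cell-type-specific regulators by RSS
#'
#' @param rss regulons x cell-types matrix from [compute_rss()].
#' @param cell_type one of the matrix's column names.
#' @param n how many regulators to return (default 5); fewer are returned
#'   when fewer exist. Ties are broken alphabetically by regulon name.
#' @return data.frame (regulon, rss), highest first.
#' @export
top_regulators <- function(rss, cell_type, n = 5L) {
  stopifnot(is.matrix(rss))
  n <- check_count(n, "n")
  if (!cell_type %in% colnames(rss))
    stop_invalid("unknown cell type '", cell_type, "'")
  v <- rss[, cell_type]
  ord <- order(-v, rownames(rss))
  take <- utils::head(ord, n)
  data.frame(regulon = rownames(rss)[take], rss = unname(v[take]),
             row.names = NULL)
}
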