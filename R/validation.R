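#' Permutation test of regulon coexpression across a dataset panel
#'
#' In each dataset, the statistic is the mean pairwise Spearman correlation
#' among the regulon's genes. Its null distribution comes from
#' \code{n_perm} random gene sets of the same size drawn from that
#' dataset's genes, and the p-value uses the add-one rule
#' p = (1 + #\{perm >= observed\}) / (1 + n_perm), so it can never be 0.
#'
#' @param regulon a \code{regulon} object, or a character vector of genes
#'   (a TF plus targets).
#' @param panel list of sample x gene expression matrices, e.g. from
#'   [simulate_validation_panel()].
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param alpha per-dataset significance level (default 0.05).
#' @param seed RNG seed.
#' @return list of class \code{panel_result}: \code{per_dataset}
#'   (data.frame dataset, statistic, p, n_genes_used), plus the summary
#'   fields of [summarize_validation()] at level \code{alpha}.
#' @export
panel_coexpression_test <- function(regulon, panel, n_perm = 1000L,
                                    alpha = 0.05, seed = 1L) {
  genes <- if (inherits(regulon, "regulon"))
    unique(c(regulon$tf, regulon$targets)) else unique(as.character(regulon))
  if (length(genes) < 2L)
    stop_invalid("regulon must contain >= 2 genes")
  stopifnot(is.list(panel), length(panel) >= 1L)
  n_perm <- check_count(n_perm, "n_perm")
  if (n_perm < 100L) warning("n_perm < 100 gives coarse p-values")

  rows <- list()
  for (d in seq_along(panel)) {
    mat <- panel[[d]]
    if (methods::is(mat, "sparseMatrix")) mat <- as.matrix(mat)
    present <- intersect(genes, colnames(mat))
    if (length(present) < 2L) {
      warning("dataset ", d, ": fewer than 2 regulon genes present; skipped")
      next
    }
    # Spearman = Pearson on ranks; one full gene-gene matrix serves both the
    # observed statistic and every permutation draw
    ranks <- apply(mat, 2L, rank)
    cmat <- suppressWarnings(stats::cor(ranks))
    cmat[!is.finite(cmat)] <- 0
    mean_off <- function(idx) {
      sub <- cmat[idx, idx]
      sum(sub[upper.tri(sub)]) / (length(idx) * (length(idx) - 1L) / 2L)
    }
    obs <- mean_off(match(present, colnames(mat)))
    set.seed(derive_seed(seed, d))
    perm <- vapply(seq_len(n_perm), function(i)
      mean_off(sample.int(ncol(mat), length(present))), numeric(1))
    p <- (1 + sum(perm >= obs)) / (1 + n_perm)
    rows[[length(rows) + 1L]] <- data.frame(
      dataset = d, statistic = obs, p = p, n_genes_used = length(present))
  }
  if (length(rows) == 0L)
    stop_invalid("regulon has fewer than 2 genes in every panel dataset")
  per_dataset <- do.call(rbind, rows)
  res <- summarize_validation(per_dataset$p, alpha = alpha)
  res$per_dataset <- per_dataset
  res
}

#' Summarize per-dataset coexpression p-values
#'
#' Counts datasets significant at \code{alpha} and, when a background pair
#' of counts is supplied, compares the regulon's hit rate against it with a
#' two-sided Fisher's exact test on the 2x2 table
#' \code{[[n_significant, n_total - n_significant], [k_bg, n_bg - k_bg]]}.
#'
#' @param p_values per-dataset p-values in (0, 1].
#' @param alpha significance level (strict: p < alpha counts).
#' @param background optional \code{c(k_bg, n_bg)}: significant and total
#'   dataset counts of a comparison regulon or reference rate.
#' @return list of class \code{panel_result} with \code{n_significant},
#'   \code{n_total}, \code{summary} (a "k datasets (out of N)" string) and
#'   \code{fisher_p} (NA without a background).
#' @export
summarize_validation <- function(p_values, alpha = 0.05, background = NULL) {
  if (length(p_values) == 0L) stop_invalid("empty p-value list")
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    stop_invalid("p-values must lie in (0, 1]")
  n_sig <- sum(p_values < alpha)
  n_tot <- length(p_values)
  fisher_p <- NA_real_
  if (!is.null(background)) {
    stopifnot(length(background) == 2L)
    k_bg <- check_count(background[1L], "background k", min = 0L)
    n_bg <- check_count(background[2L], "background n", min = 1L)
    if (k_bg > n_bg)
      stop_invalid("background counts inconsistent: k (", k_bg,
                   ") > n (", n_bg, ")")
    fisher_p <- fisher_exact_2x2(n_sig, n_tot - n_sig, k_bg, n_bg - k_bg)
  }
  structure(list(n_significant = n_sig, n_total = n_tot,
                 summary = sprintf("%d datasets (out of %d)", n_sig, n_tot),
                 alpha = alpha, fisher_p = fisher_p),
            class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  cat("panel_result: significantly coexpressed in", x$summary,
      "at alpha =", x$alpha, "\n")
  if (!is.na(x$fisher_p))
    cat("  Fisher's exact test vs background: p =",
        format(x$fisher_p, digits = 4), "\n")
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric enumeration over the table family with the observed
#' margins; the two-sided p-value sums the probabilities of all tables at
#' most as probable as the observed one (point-probability rule, with a
#' 1e-12 relative tolerance for floating-point ties).
#'
#' @param a,b,c,d cell counts of the table \code{rbind(c(a, b), c(c, d))}.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_invalid("table cells must be non-negative integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (n == 0L) return(1)
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  x <- lo:hi
  # log hypergeometric pmf for each admissible top-left cell
  logp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  p_obs <- logp[x == a]
  sum(exp(logp[logp <= p_obs + 1e-12 * abs(p_obs) + 1e-300]))
}

#' Fetch the GSE98816 supplementary counts table from GEO
#'
#' Downloads the series' supplementary expression table (mouse brain
#' vasculature single cells) into \code{dest_dir}. Requires network access;
#' offline use should point [read_counts_table()] at a local copy.
#'
#' @param dest_dir directory to download into.
#' @param base_url GEO supplementary-file directory for the series.
#' @return path to the downloaded file.
#' @export
fetch_gse98816 <- function(dest_dir = tempdir(),
                           base_url = "https://ftp.ncbi.nlm.nih.gov/geo/series/GSE98nnn/GSE98816/suppl/") {
  listing <- tryCatch(readLines(base_url, warn = FALSE),
                      error = function(e)
                        stop_io("cannot reach GEO at ", base_url, ": ",
                                conditionMessage(e)))
  files <- unlist(regmatches(listing, gregexpr("GSE98816[A-Za-z0-9_.%-]*\\.gz",
                                               listing)))
  files <- unique(files)
  if (length(files) == 0L)
    stop_io("no supplementary .gz file found under ", base_url)
  f <- utils::URLdecode(files[[1L]])
  dest <- file.path(dest_dir, basename(f))
  utils::download.file(paste0(base_url, f), dest, mode = "wb", quiet = TRUE)
  dest
}

#' Read a genes-by-cells counts table (plain or gzipped TSV)
#'
#' Reads a GEO-style expression table with gene symbols in the first column
#' and one column per cell, returning the pipeline's cells x genes sparse
#' orientation.
#'
#' @param path TSV or TSV.gz file.
#' @return cells x genes \code{dgCMatrix}.
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) stop_io("missing counts table '", path, "'")
  df <- read.delim(path, row.names = 1L, check.names = FALSE)
  m <- t(as.matrix(df))
  as_expression_matrix(m)
}
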