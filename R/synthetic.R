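#' Construct a ground-truth regulatory network object
#'
#' @param tfs character vector of TF symbols.
#' @param targets named list mapping each TF to its target genes.
#' @param type_activity named list mapping each cell type to its active TFs.
#' @param background_genes genes regulated by no TF.
#' @return object of class \code{ground_truth_network}.
#' @export
new_ground_truth_network <- function(tfs, targets, type_activity, background_genes) {
  stopifnot(is.character(tfs), is.list(targets), is.list(type_activity))
  for (tf in names(targets)) {
    if (tf %in% targets[[tf]])
      stop_invalid("TF ", tf, " appears in its own target set")
  }
  active <- unique(unlist(type_activity))
  if (!all(active %in% tfs))
    stop_invalid("type_activity references TFs absent from `tfs`")
  structure(list(tfs = tfs, targets = targets, type_activity = type_activity,
                 background_genes = background_genes),
            class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat("ground_truth_network:", length(x$tfs), "TFs,",
      length(unlist(x$targets)), "target assignments,",
      length(x$type_activity), "cell types,",
      length(x$background_genes), "background genes\n")
  invisible(x)
}

#' All gene symbols of a ground-truth network, TFs first
#' @param gt a \code{ground_truth_network}.
#' @return character vector of unique gene symbols.
#' @export
network_genes <- function(gt) {
  unique(c(gt$tfs, unlist(gt$targets, use.names = FALSE), gt$background_genes))
}

#' True TF-target edge table of a ground-truth network
#' @param gt a \code{ground_truth_network}.
#' @return data.frame with columns \code{tf}, \code{target}.
#' @export
network_edges <- function(gt) {
  do.call(rbind, c(list(data.frame(tf = character(), target = character())),
                   lapply(names(gt$targets), function(tf)
                     data.frame(tf = tf, target = gt$targets[[tf]]))))
}

#' Generate a ground-truth regulatory network with planted cell-type activity
#'
#' Each cell type receives at least one private active TF (TFs are dealt to
#' types round-robin), so type identity is recoverable downstream. Gene
#' symbols are synthetic (\code{TF001}, \code{G0001}); with
#' \code{disjoint = TRUE} every TF gets its own block of target genes.
#'
#' @param n_tfs number of TFs (must be >= \code{n_types}).
#' @param n_targets_per_tf targets per TF.
#' @param n_types number of cell types.
#' @param n_background unregulated genes added to the gene universe.
#' @param disjoint if TRUE target sets are pairwise disjoint; if FALSE each
#'   TF samples its targets from a shared pool, so sets may overlap.
#' @param seed RNG seed; the output is a pure function of the arguments.
#' @return a \code{ground_truth_network}.
#' @export
generate_network <- function(n_tfs, n_targets_per_tf, n_types,
                             n_background = 0L, disjoint = TRUE, seed = 1L) {
  n_tfs <- check_count(n_tfs, "n_tfs")
  n_targets_per_tf <- check_count(n_targets_per_tf, "n_targets_per_tf")
  n_types <- check_count(n_types, "n_types")
  n_background <- check_count(n_background, "n_background", min = 0L)
  if (n_tfs < n_types)
    stop_invalid("n_tfs (", n_tfs, ") must be >= n_types (", n_types, ")")

  set.seed(seed)
  tfs <- sprintf("TF%03d", seq_len(n_tfs))
  if (disjoint) {
    pool <- sprintf("G%04d", seq_len(n_tfs * n_targets_per_tf))
    targets <- split(pool, rep(seq_len(n_tfs), each = n_targets_per_tf))
  } else {
    # shared pool roughly half the disjoint size, so overlaps actually occur
    pool_size <- max(n_targets_per_tf, ceiling(n_tfs * n_targets_per_tf / 2))
    pool <- sprintf("G%04d", seq_len(pool_size))
    targets <- lapply(seq_len(n_tfs), function(i) sort(sample(pool, n_targets_per_tf)))
  }
  names(targets) <- tfs
  n_used <- length(unique(unlist(targets)))
  background <- if (n_background > 0L)
    sprintf("G%04d", n_used + seq_len(n_background)) else character()

  types <- sprintf("type%d", seq_len(n_types))
  type_activity <- split(tfs, rep_len(types, n_tfs))[types]

  new_ground_truth_network(tfs, targets, type_activity, background)
}

#' Simulation parameters for the synthetic count generator
#'
#' Counts are negative binomial with variance \eqn{\mu + \mu^2/\theta};
#' dropout is zero-inflation applied after sampling. Defaults define the
#' package's reference scenario, emulating a deeply sequenced full-length
#' protocol: 200 cells per type, a 4-fold up-regulation of each active TF
#' and its targets in its own type, moderate overdispersion (theta = 5)
#' and 10\% technical dropout.
#'
#' Per-gene baseline abundances are log-normal around \code{nb_mean_base}
#' (geometric-mean preserving), reflecting the orders-of-magnitude spread of
#' real transcript abundances; set \code{mean_sd_log = 0} for exactly
#' exchangeable genes.
#'
#' @param n_cells_per_type cells simulated per cell type.
#' @param nb_mean_base baseline negative-binomial mean per gene.
#' @param nb_dispersion NB size parameter theta; variance = mu + mu^2/theta.
#' @param activity_fold multiplicative fold-up (>= 1) of active TFs and their
#'   targets in the type where the TF is active.
#' @param dropout_rate probability that an observed count is zeroed.
#' @param mean_sd_log sd (log scale) of the per-gene baseline abundance.
#' @param seed RNG seed.
#' @return list of validated parameters, class \code{simulation_params}.
#' @export
simulation_params <- function(n_cells_per_type = 200L, nb_mean_base = 2,
                              nb_dispersion = 5, activity_fold = 4,
                              dropout_rate = 0.1, mean_sd_log = 0.5,
                              seed = 1L) {
  n_cells_per_type <- check_count(n_cells_per_type, "n_cells_per_type")
  if (!is.numeric(nb_mean_base) || nb_mean_base <= 0)
    stop_invalid("`nb_mean_base` must be positive")
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0)
    stop_invalid("`nb_dispersion` must be positive")
  if (!is.numeric(activity_fold) || activity_fold < 1)
    stop_invalid("`activity_fold` must be >= 1")
  dropout_rate <- check_prob(dropout_rate, "dropout_rate")
  if (!is.numeric(mean_sd_log) || mean_sd_log < 0)
    stop_invalid("`mean_sd_log` must be >= 0")
  structure(list(n_cells_per_type = n_cells_per_type, nb_mean_base = nb_mean_base,
                 nb_dispersion = nb_dispersion, activity_fold = activity_fold,
                 dropout_rate = dropout_rate, mean_sd_log = mean_sd_log,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Simulate a single-cell count matrix from a planted network
#'
#' For every cell of type t, each gene's NB mean is the baseline, multiplied
#' by \code{activity_fold} when the gene is a TF active in t or one of that
#' TF's targets. Counts are then zeroed independently with probability
#' \code{dropout_rate}.
#'
#' @param gt a \code{ground_truth_network}.
#' @param params a \code{simulation_params} object.
#' @return list with \code{counts} (cells x genes \code{dgCMatrix}) and
#'   \code{labels} (character vector of cell types, one per cell).
#' @export
simulate_dataset <- function(gt, params = simulation_params()) {
  stopifnot(inherits(gt, "ground_truth_network"),
            inherits(params, "simulation_params"))
  genes <- network_genes(gt)
  types <- names(gt$type_activity)
  n_cells <- params$n_cells_per_type * length(types)

  # per-type mean multiplier for each gene
  fold <- matrix(1, nrow = length(types), ncol = length(genes),
                 dimnames = list(types, genes))
  for (ct in types) {
    for (tf in gt$type_activity[[ct]]) {
      fold[ct, c(tf, gt$targets[[tf]])] <- params$activity_fold
    }
  }

  set.seed(params$seed)
  # gene-specific baseline abundances, log-normal with preserved geometric mean
  base_mu <- params$nb_mean_base *
    exp(rnorm(length(genes), mean = 0, sd = params$mean_sd_log))
  labels <- rep(types, each = params$n_cells_per_type)
  counts <- matrix(0L, nrow = n_cells, ncol = length(genes),
                   dimnames = list(sprintf("cell_%05d", seq_len(n_cells)), genes))
  for (ct in types) {
    idx <- which(labels == ct)
    mu <- rep(base_mu * fold[ct, ], each = length(idx))
    counts[idx, ] <- rnbinom(length(idx) * length(genes),
                             mu = mu, size = params$nb_dispersion)
  }
  if (params$dropout_rate > 0) {
    keep <- matrix(rbinom(length(counts), 1L, 1 - params$dropout_rate),
                   nrow = n_cells)
    counts <- counts * keep
  }
  list(counts = as_expression_matrix(counts), labels = labels)
}

#' Simulate a panel of small validation datasets with shared coexpression
#'
#' Emulates a compendium of independent expression datasets against which a
#' regulon's coexpression can be checked. In \code{n_shared_signal} of the
#' datasets, each regulon's genes (TF plus targets) load on a dataset- and
#' regulon-specific latent factor, so they are genuinely coexpressed; in the
#' remaining datasets all genes are independent.
#'
#' @param gt a \code{ground_truth_network}.
#' @param n_datasets number of datasets in the panel.
#' @param n_shared_signal how many datasets carry the planted coexpression.
#' @param seed RNG seed.
#' @param n_samples samples (columns of a bulk compendium; rows here) per dataset.
#' @param factor_sd strength of the latent factor on the log-mean scale.
#' @param nb_mean baseline NB mean of panel counts.
#' @param nb_dispersion NB size parameter theta.
#' @return list of \code{n_datasets} sample x gene count matrices.
#' @export
simulate_validation_panel <- function(gt, n_datasets, n_shared_signal,
                                      seed = 1L, n_samples = 60L,
                                      factor_sd = 0.8, nb_mean = 20,
                                      nb_dispersion = 10) {
  stopifnot(inherits(gt, "ground_truth_network"))
  n_datasets <- check_count(n_datasets, "n_datasets")
  n_shared_signal <- check_count(n_shared_signal, "n_shared_signal", min = 0L)
  if (n_shared_signal > n_datasets)
    stop_invalid("n_shared_signal (", n_shared_signal,
                 ") exceeds n_datasets (", n_datasets, ")")
  n_samples <- check_count(n_samples, "n_samples", min = 3L)
  genes <- network_genes(gt)

  set.seed(seed)
  lapply(seq_len(n_datasets), function(d) {
    logmu <- matrix(0, nrow = n_samples, ncol = length(genes),
                    dimnames = list(sprintf("s%03d", seq_len(n_samples)), genes))
    if (d <= n_shared_signal) {
      for (tf in gt$tfs) {
        f <- rnorm(n_samples, sd = factor_sd)
        logmu[, c(tf, gt$targets[[tf]])] <-
          logmu[, c(tf, gt$targets[[tf]])] + f
      }
    }
    mu <- nb_mean * exp(logmu)
    m <- matrix(rnbinom(length(mu), mu = mu, size = nb_dispersion),
                nrow = n_samples, dimnames = dimnames(logmu))
    as_expression_matrix(m)
  })
}
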