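make_counts <- function(m) as_expression_matrix(m)

test_that("gene filter applies the expressing-cell-fraction rule", {
  # 3186 cells: a gene seen in 3 cells is below 0.1% (3.186), one in 4 is kept
  n <- 3186
  m <- matrix(0, n, 3, dimnames = list(sprintf("c%d", 1:n), c("g3", "g4", "gAll")))
  m[1:3, "g3"] <- 1
  m[1:4, "g4"] <- 1
  m[, "gAll"] <- 1
  out <- filter_genes(make_counts(m), 0.001)
  expect_identical(colnames(out), c("g4", "gAll"))

  # zero threshold keeps everything, including an all-zero gene
  expect_identical(colnames(filter_genes(make_counts(m), 0)), colnames(m))
  # any positive threshold removes an all-zero gene
  m0 <- cbind(m, gZero = 0)
  out0 <- filter_genes(make_counts(m0), 1e-9)
  expect_false("gZero" %in% colnames(out0))
  # monotone: raising the threshold never adds a gene
  prev <- colnames(m0)
  for (f in c(0, 0.0005, 0.001, 0.01, 0.5)) {
    kept <- colnames(filter_genes(make_counts(m0), f))
    expect_true(all(kept %in% prev))
    prev <- kept
  }
  # no gene reaches a full-support requirement once gAll is excluded
  expect_error(filter_genes(make_counts(m[, c("g3", "g4")]), 1),
               class = "regulonscape_invalid_argument")
})

test_that("normalization matches the hand-computed scaling on a toy matrix", {
  m <- matrix(c(1, 0, 2, 4,
                2, 1, 0, 1,
                3, 1, 1, 5), nrow = 4, ncol = 3,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  ns <- suppressWarnings(normalize_and_select(make_counts(m), n_hvg = 3))
  totals <- rowSums(m)
  expected <- log1p(m / totals * 1e4)
  expect_equal(ns$normed, expected, tolerance = 1e-12)
  # pre-log scaled totals are the fixed constant
  expect_equal(unname(rowSums(expm1(ns$normed))), rep(1e4, 4), tolerance = 1e-8)
})

test_that("constant genes are never selected as variable", {
  set.seed(1)
  m <- cbind(matrix(rpois(200 * 5, 5), 200, 5), const = 2)
  dimnames(m) <- list(sprintf("c%d", 1:200), c(paste0("g", 1:5), "const"))
  ns <- suppressWarnings(normalize_and_select(make_counts(m), n_hvg = 6))
  expect_false("const" %in% ns$hvg)
})

test_that("a planted bimodal gene outranks an exchangeable gene", {
  gt <- generate_network(2, 4, 2, 30, seed = 2)
  marker <- gt$type_activity$type1[1]
  bg <- gt$background_genes[1]
  for (s in 1:3) {
    sim <- simulate_dataset(gt, simulation_params(
      n_cells_per_type = 100, activity_fold = 6, seed = s))
    ns <- suppressWarnings(normalize_and_select(sim$counts, n_hvg = ncol(sim$counts)))
    expect_lt(match(marker, ns$hvg), match(bg, ns$hvg))
  }
})

test_that("two well-separated blobs yield exactly two reproducible clusters", {
  set.seed(4)
  n <- 100
  blob <- rbind(matrix(rnorm(n * 20, 0), n, 20),
                matrix(rnorm(n * 20, 8), n, 20))
  dimnames(blob) <- list(sprintf("c%d", 1:(2 * n)), sprintf("g%d", 1:20))
  ann <- embed_and_cluster(blob, n_pcs = 5, resolution = 0.8, seed = 1)
  expect_length(unique(ann$cluster), 2)
  expect_identical(sort(unique(ann$cluster)), c(0L, 1L))
  # bit-for-bit reproducible at a fixed seed
  ann2 <- embed_and_cluster(blob, n_pcs = 5, resolution = 0.8, seed = 1)
  expect_identical(ann$cluster, ann2$cluster)
  # same partition under a different seed on this separable toy
  ann3 <- embed_and_cluster(blob, n_pcs = 5, resolution = 0.8, seed = 99)
  expect_equal(mclust::adjustedRandIndex(ann$cluster, ann3$cluster), 1)
  expect_error(embed_and_cluster(blob, n_pcs = 20),
               class = "regulonscape_invalid_argument")
})

test_that("planted four-type data is recovered with high agreement", {
  sim <- default_sim(1)
  ns <- default_normed(1)
  ann <- embed_and_cluster(ns$normed, n_pcs = 10, resolution = 0.8,
                           seed = 1, hvg = ns$hvg)
  expect_gte(mclust::adjustedRandIndex(ann$cluster, sim$labels), 0.9)
})

test_that("wilcoxon markers match the exact permutation oracle on a toy", {
  vals <- c(5, 6, 7, 0, 0, 1)
  m <- cbind(g = vals, filler1 = c(1, 2, 1, 2, 1, 2), filler2 = 6:1)
  rownames(m) <- sprintf("c%d", 1:6)
  ann <- structure(list(
    cluster = setNames(c(0L, 0L, 0L, 1L, 1L, 1L), rownames(m)),
    cell_type = c(`0` = "unassigned", `1` = "unassigned"),
    embedding = NULL), class = "cell_annotation")
  mk <- find_markers(m, ann, min_logfc = -Inf, alpha = 1)

  # exact p: enumerate all choose(6,3) group assignments of the rank sum
  ranksum_obs <- sum(rank(vals)[1:3])
  combos <- combn(6, 3)
  sums <- apply(combos, 2, function(idx) sum(rank(vals)[idx]))
  mu <- mean(sums)
  p_exact <- mean(abs(sums - mu) >= abs(ranksum_obs - mu))
  got <- mk[mk$cluster == 0 & mk$gene == "g", ]
  expect_equal(got$p, p_exact, tolerance = 1e-10)
  expect_gt(got$logfc, 0)
})

test_that("a gene exclusive to one cluster is its top marker", {
  set.seed(2)
  m <- matrix(rpois(60 * 4, 2), 60, 4,
              dimnames = list(sprintf("c%d", 1:60), paste0("g", 1:4)))
  m[1:30, "g1"] <- m[1:30, "g1"] + 50
  ann <- structure(list(
    cluster = setNames(rep(c(0L, 1L), each = 30), rownames(m)),
    cell_type = c(`0` = "unassigned", `1` = "unassigned"),
    embedding = NULL), class = "cell_annotation")
  mk <- find_markers(m, ann, min_logfc = 0, alpha = 0.05)
  top_a <- mk[mk$cluster == 0, ][1, ]
  expect_identical(top_a$gene, "g1")
  expect_gt(top_a$logfc, 0)
  # a cluster below 3 cells is skipped with a warning
  ann$cluster[1:58] <- 0L
  expect_warning(find_markers(m, ann, min_logfc = 0, alpha = 1), "fewer than 3")
})

test_that("marker p-values are calibrated on exchangeable data", {
  false_pos <- 0L
  n_tests <- 0L
  for (s in 1:20) {
    set.seed(s)
    m <- matrix(rpois(40 * 10, 4), 40, 10,
                dimnames = list(sprintf("c%d", 1:40), paste0("g", 1:10)))
    ann <- structure(list(
      cluster = setNames(rep(c(0L, 1L), each = 20), rownames(m)),
      cell_type = c(`0` = "unassigned", `1` = "unassigned"),
      embedding = NULL), class = "cell_annotation")
    mk <- find_markers(m, ann, min_logfc = -Inf, alpha = 0.05)
    false_pos <- false_pos + nrow(mk)
    n_tests <- n_tests + 20L
  }
  expect_lte(false_pos / n_tests, 0.05)
})

test_that("reference-marker annotation labels block-diagonal clusters", {
  set.seed(7)
  n <- 30
  m <- matrix(rpois(3 * n * 3, 1), 3 * n, 3,
              dimnames = list(sprintf("c%d", 1:(3 * n)), c("Ma", "Mb", "Mc")))
  m[1:n, "Ma"] <- m[1:n, "Ma"] + 20
  m[(n + 1):(2 * n), "Mb"] <- m[(n + 1):(2 * n), "Mb"] + 20
  m[(2 * n + 1):(3 * n), "Mc"] <- m[(2 * n + 1):(3 * n), "Mc"] + 20
  ann <- structure(list(
    cluster = setNames(rep(0:2, each = n), rownames(m)),
    cell_type = setNames(rep("unassigned", 3), 0:2),
    embedding = NULL), class = "cell_annotation")
  ref <- data.frame(cell_type = c("alpha", "beta", "gamma"),
                    gene = c("Ma", "Mb", "Mc"))
  out <- annotate_clusters(m, ann, ref)
  expect_identical(unname(out$cell_type), c("alpha", "beta", "gamma"))

  # exact score ties give "unassigned"
  ref_tie <- data.frame(cell_type = c("x", "y"), gene = c("Ma", "Ma"))
  out_tie <- annotate_clusters(m, ann, ref_tie)
  expect_identical(unname(out_tie$cell_type[1]), "unassigned")

  # absent reference genes warn and are ignored
  ref_missing <- data.frame(cell_type = c("alpha", "ghost"),
                            gene = c("Ma", "NotAGene"))
  expect_warning(annotate_clusters(m, ann, ref_missing), "NotAGene")
})

test_that("planted targets are recovered among their type's markers", {
  sim <- default_sim(1)
  gt <- default_gt(1)
  ns <- default_normed(1)
  ann <- embed_and_cluster(ns$normed, seed = 1, hvg = ns$hvg)
  mk <- find_markers(ns$normed, ann, min_logfc = 0.25, alpha = 0.05)
  # map clusters to majority truth type
  for (cl in unique(ann$cluster)) {
    ct <- names(which.max(table(sim$labels[ann$cluster == cl])))
    planted <- unlist(lapply(gt$type_activity[[ct]],
                             function(tf) c(tf, gt$targets[[tf]])))
    planted <- intersect(planted, colnames(ns$normed))
    found <- mk$gene[mk$cluster == cl]
    expect_gte(mean(planted %in% found), 0.8)
  }
})
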