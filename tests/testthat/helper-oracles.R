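# Independent oracles used across test files. Each is written from the
# definition of the quantity, not by calling the package's implementation.

# Jensen-Shannon divergence, base 2, direct arithmetic
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  term <- function(a) {
    out <- 0
    for (i in seq_along(a)) if (a[i] > 0) out <- out + a[i] * log2(a[i] / m[i])
    unname(out)
  }
  (term(unname(p)) + term(unname(q))) / 2
}

oracle_rss <- function(ras_col, labels, type) {
  p <- unname(ras_col) / sum(ras_col)
  q <- as.numeric(labels == type)
  q <- q / sum(q)
  1 - sqrt(oracle_jsd(p, q))
}

# CSI by exhaustive O(N^3) counting
oracle_csi <- function(pcc, offset = 0.05) {
  n <- nrow(pcc)
  out <- matrix(0, n, n, dimnames = dimnames(pcc))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) { out[a, b] <- 1; next }
    thr <- pcc[a, b] - offset
    cnt <- 0
    for (cc in seq_len(n))
      if (pcc[a, cc] < thr && pcc[b, cc] < thr) cnt <- cnt + 1
    out[a, b] <- cnt / n
  }
  out
}

# recovery-AUC by explicit step-curve enumeration over the top-k ranks
oracle_auc <- function(positions, n_genes, top_fraction, regulon_size) {
  k <- ceiling(top_fraction * n_genes)
  area <- 0
  for (x in seq_len(k)) area <- area + sum(positions <= x)
  m <- min(regulon_size, k)
  max_area <- 0
  for (x in seq_len(k)) max_area <- max_area + min(x, m)
  area / max_area
}

# two-sided Fisher p by dhyper enumeration (point-probability rule)
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (n == 0) return(1)
  x <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(x, r1, r2, c1)
  p_obs <- probs[x == a]
  sum(probs[probs <= p_obs * (1 + 1e-12) + 1e-300])
}

# independent dense MCL: same algorithm contract, different code path and a
# different (attractor-row) cluster read-out
oracle_mcl <- function(adj, inflation = 2, self_loop = 1, prune = 1e-6,
                       tol = 1e-8, max_iter = 100) {
  n <- nrow(adj)
  m <- adj
  for (i in seq_len(n)) m[i, i] <- m[i, i] + self_loop
  for (j in seq_len(n)) m[, j] <- m[, j] / sum(m[, j])
  for (it in seq_len(max_iter)) {
    prev <- m
    m <- m %*% m
    m <- m ^ inflation
    m[m < prune] <- 0
    for (j in seq_len(n)) m[, j] <- m[, j] / sum(m[, j])
    if (max(abs(m - prev)) < tol) break
  }
  attractors <- which(diag(m) > prune)
  clusters <- lapply(attractors, function(a) which(m[a, ] > prune))
  # merge overlapping attractor systems
  merged <- list()
  for (cl in clusters) {
    hit <- which(vapply(merged, function(x) length(intersect(x, cl)) > 0,
                        logical(1)))
    if (length(hit)) {
      merged[[hit[1]]] <- sort(unique(c(unlist(merged[hit]), cl)))
      merged <- merged[-hit[-1]]
    } else merged[[length(merged) + 1]] <- sort(cl)
  }
  # nodes attracted to no attractor (isolated after pruning) become singletons
  left <- setdiff(seq_len(n), unlist(merged))
  for (v in left) merged[[length(merged) + 1]] <- v
  lapply(merged, function(idx) sort(rownames(adj)[idx]))
}

# canonical form of a partition (list of character vectors) for comparison
canon_partition <- function(cl) {
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, `[`, character(1), 1L))]
}

random_symmetric_pcc <- function(n) {
  m <- matrix(stats::runif(n * n, -1, 1), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(paste0("R", seq_len(n)), paste0("R", seq_len(n)))
  m
}
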