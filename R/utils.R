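#' @keywords internal
"_PACKAGE"

#' @import Matrix
#' @importFrom stats cor prcomp wilcox.test p.adjust t.test sd var quantile
#'   rnbinom rbinom rnorm hclust cutree as.dist loess predict dhyper
#' @importFrom methods as is
#' @importFrom utils read.delim write.table
NULL

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("regulonscape_invalid_argument", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("regulonscape_io_error", "error")))
}

# scalar positive-integer check used by simulation and scoring entry points
check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    stop_invalid("`", name, "` must be a single integer >= ", min, " (got ", deparse(x), ")")
  as.integer(x)
}

check_prob <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    stop_invalid("`", name, "` must be a probability in [0, 1]")
  as.numeric(x)
}

# coefficient of variation; NA when the mean is zero (dropped by callers)
cv <- function(x) {
  m <- mean(x)
  if (!is.finite(m) || m == 0) return(NA_real_)
  stats::sd(x) / m
}

# deterministic sub-seed derivation, kept below .Machine$integer.max
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + k) %% 2147483647L)
}
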