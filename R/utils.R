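`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates, restores. With `seed = NULL`
#' the expression runs against the current RNG stream.
#' @param seed integer or NULL
#' @param code expression
#' @return value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_lever2p <- function(class, msg, ...) {
  stop(structure(class = c(class, "lever2p_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# trailing rolling sum with truncated left edge
rolling_sum_trailing <- function(x, w) {
  if (w <= 1) return(x)
  cs <- cumsum(x)
  out <- cs
  if (length(x) > w) out[(w + 1):length(x)] <- cs[(w + 1):length(x)] - cs[1:(length(x) - w)]
  out
}

# centered moving average with truncated edges
boxcar_smooth <- function(x, w) {
  if (w <= 1) return(x)
  h <- (w - 1) %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# bootstrap resample-count matrix: n_boot x n, row sums n, divided by n it is
# the weight matrix mapping trial values to bootstrap means
boot_count_matrix <- function(n, n_boot) {
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  rows <- rep(seq_len(n_boot), each = n)
  lin <- (idx - 1L) * n_boot + rows   # column-major cell of an n_boot x n matrix
  matrix(tabulate(lin, nbins = n * n_boot), n_boot, n)
}

# faster: bootstrap means of a vector
boot_means <- function(values, n_boot) {
  n <- length(values)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  colMeans(matrix(values[idx], nrow = n, ncol = n_boot))
}

# bootstrap medians of a vector
boot_medians <- function(values, n_boot, sample_size = length(values)) {
  n <- length(values)
  idx <- matrix(sample.int(n, sample_size * n_boot, replace = TRUE), nrow = n_boot)
  apply(idx, 1L, function(j) stats::median(values[j]))
}

percentile_ci <- function(x, level = 95) {
  a <- (100 - level) / 200
  stats::quantile(x, c(a, 1 - a), names = FALSE, na.rm = TRUE)
}
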