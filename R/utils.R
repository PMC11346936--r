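`%||%` <- function(a, b) if (is.null(a)) b else a

#' Conversion factor from poise to pascal-second
#'
#' The empirical Walburn-Schneck prefactor yields viscosity in poise;
#' multiplying by this constant converts to SI (Pa s).
#' @export
POISE_TO_PAS <- 0.1

# Blackman apodization window of length n (symmetric).
blackman_window <- function(n) {
  k <- seq_len(n) - 1
  0.42 - 0.5 * cos(2 * pi * k / (n - 1)) + 0.08 * cos(4 * pi * k / (n - 1))
}

# Run code with a local RNG state seeded by `seed`, restoring the caller's
# stream afterwards so generators never perturb user code.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# 3x3 (or k x k) spatial median filter of a matrix, replicating borders.
median_filter2 <- function(m, k = 3) {
  r <- (k - 1) %/% 2
  nr <- nrow(m); nc <- ncol(m)
  ii <- pmin(pmax(seq(1 - r, nr + r), 1), nr)
  jj <- pmin(pmax(seq(1 - r, nc + r), 1), nc)
  mp <- m[ii, jj]
  out <- m
  for (i in seq_len(nr)) {
    rows <- i:(i + 2 * r)
    block <- mp[rows, , drop = FALSE]
    for (j in seq_len(nc)) {
      out[i, j] <- median(block[, j:(j + 2 * r)])
    }
  }
  out
}

# Bilinear sample of matrix `m` at fractional (row, col) positions given in
# grid coordinate units (1-based R indices).
bilinear_at <- function(m, row, col) {
  cpp_bilinear(m, matrix(col - 1, ncol = 1), matrix(row - 1, ncol = 1))[, 1]
}

stopifnot_positive <- function(..., .names = NULL) {
  vals <- list(...)
  nms <- .names %||% sapply(substitute(list(...))[-1], deparse)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("`%s` must be a positive finite number", nms[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}
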