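# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# NULL seed leaves the RNG stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic stream splitting: every stochastic stage derives its own
# seed from the global one so stages stay reproducible independently.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 999983 * as.numeric(k)) %% 2147483587)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# Banded Toeplitz matrix of a discretized, sum-normalized Gaussian
# kernel; multiplying by it convolves along one axis with truncation at
# the borders (no renormalization), i.e. standard blur semantics.
gaussian_band <- function(n, sd, truncate = 4) {
  if (sd <= 0) return(diag(n))
  r <- max(1L, ceiling(truncate * sd))
  kern <- stats::dnorm(seq(-r, r), sd = sd)
  kern <- kern / sum(kern)
  d <- outer(seq_len(n), seq_len(n), "-") # i - j
  K <- matrix(0, n, n)
  sel <- abs(d) <= r
  K[sel] <- kern[d[sel] + r + 1L]
  K
}

# Separable Gaussian blur of a matrix (rows = y, cols = x).
blur_gaussian <- function(M, sd_x, sd_y, truncate = 4) {
  Ky <- gaussian_band(nrow(M), sd_y, truncate)
  Kx <- gaussian_band(ncol(M), sd_x, truncate)
  Ky %*% M %*% Kx
}

# 2D "same"-size convolution with zero padding via FFT. Used for the
# (non-separable) uniform circular patch.
conv2_same <- function(M, P) {
  nr <- nrow(M) + nrow(P) - 1L
  nc <- ncol(M) + ncol(P) - 1L
  Mp <- matrix(0, nr, nc)
  Pp <- matrix(0, nr, nc)
  Mp[seq_len(nrow(M)), seq_len(ncol(M))] <- M
  Pp[seq_len(nrow(P)), seq_len(ncol(P))] <- P
  full <- Re(stats::fft(stats::fft(Mp) * stats::fft(Pp), inverse = TRUE)) / (nr * nc)
  r0 <- (nrow(P) - 1L) %/% 2L
  c0 <- (ncol(P) - 1L) %/% 2L
  full[r0 + seq_len(nrow(M)), c0 + seq_len(ncol(M)), drop = FALSE]
}

# argmax over a matrix with deterministic lowest-(y, then x) tie-break.
# Returns c(x, y) in 0-based pixel coordinates and warns on ties.
argmax_xy <- function(M, context = "map") {
  mx <- max(M)
  hits <- which(M >= mx - 1e-12, arr.ind = TRUE)
  if (nrow(hits) > 1L) {
    ord <- order(hits[, 1L], hits[, 2L])
    hits <- hits[ord, , drop = FALSE]
    warnf("%s has %d tied maxima; taking lowest (y, x)", context, nrow(hits))
  }
  c(x = unname(hits[1L, 2L]) - 1L, y = unname(hits[1L, 1L]) - 1L)
}
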