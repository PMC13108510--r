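#' @importFrom stats coef cor cor.test lm.fit median pf pnorm pt qnorm rbinom
#'   rnorm runif sd setNames var
#' @importFrom utils head tail
NULL

# Run expr with a local RNG state seeded at `seed`; the caller's RNG stream is
# untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed derived from (seed, index); kept inside the
# 32-bit signed range R requires.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483563L)
}

# Column-wise z-scoring; zero-variance columns become all-zero.
zscore_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, s, "/")
}

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

# Zero-phase Butterworth filtering of each column of `x` (frame x series).
# `type` is "pass" or "stop"; `band_hz` a length-2 increasing vector; `fs` in
# Hz. Order is the order of the underlying low-pass prototype.
butter_filtfilt <- function(x, band_hz, fs, type = c("pass", "stop"),
                            order = 2) {
  type <- match.arg(type)
  nyq <- fs / 2
  stop_if(length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[2] <= band_hz[1] ||
            band_hz[2] >= nyq,
          "frequency band must satisfy 0 < low < high < Nyquist (",
          signif(nyq, 4), " Hz)")
  filt <- signal::butter(order, band_hz / nyq, type = type)
  x <- as.matrix(x)
  n <- nrow(x)
  # reflect-pad to tame filtfilt edge transients
  pad <- min(n - 1L, 3L * max(length(filt$a), length(filt$b)) * 10L)
  out <- apply(x, 2, function(col) {
    ext <- c(2 * col[1] - rev(col[2:(pad + 1)]),
             col,
             2 * col[n] - rev(col[(n - pad):(n - 1)]))
    y <- signal::filtfilt(filt, ext)
    y[(pad + 1):(pad + n)]
  })
  matrix(out, nrow = n, dimnames = dimnames(x))
}

# Upper-triangle (excluding diagonal) of a square matrix as a vector,
# column-major order; stable across callers so edge indices line up.
upper_tri_vec <- function(m) {
  m[upper.tri(m)]
}

# Number of off-diagonal edges for p regions.
n_edges <- function(p) p * (p - 1L) / 2L
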