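# internal helpers shared across modules

# write-temp-then-rename so interrupted runs never leave truncated files
atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("atomic rename failed for ", path, call. = FALSE)
  invisible(path)
}

# pairwise Euclidean distances between rows of two 2-column matrices
pair_dist <- function(a, b = a) {
  a <- as.matrix(a); b <- as.matrix(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

# Cholesky with escalating diagonal jitter; base jitter 1e-8 applied first
# so near-duplicate locations do not break positive-definiteness
chol_jitter <- function(S, jitter = 1e-8, max_tries = 6L) {
  d <- nrow(S)
  for (k in seq_len(max_tries)) {
    R <- tryCatch(chol(S + diag(jitter, d)), error = function(e) NULL)
    if (!is.null(R)) {
      attr(R, "jitter") <- jitter
      return(R)
    }
    jitter <- if (jitter == 0) 1e-8 else jitter * 100
  }
  stop("covariance matrix not positive definite even after jitter ",
       format(jitter), call. = FALSE)
}

# one draw (or n draws as columns) from N(mu, S) via Cholesky
rmvn <- function(n, mu, S, jitter = 1e-8) {
  d <- length(mu)
  R <- chol_jitter(S, jitter)
  Z <- matrix(stats::rnorm(n * d), d, n)
  sweep(crossprod(R, Z), 1, mu, "+")
}

# simulate a zero-mean GP with exponential correlation at given points,
# reusing a precomputed Cholesky when drawing many replicate fields
gp_chol <- function(coords, range_km, jitter = 1e-8) {
  C <- exp(-pair_dist(coords) / range_km)
  chol_jitter(C, jitter)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
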