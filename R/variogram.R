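#' Empirical (Matheron) semivariogram of cluster-level residuals
#'
#' Classical moment estimator: for each distance bin, half the mean
#' squared difference of residuals over all cluster pairs falling in the
#' bin. Used to check for residual spatial correlation after covariate
#' adjustment: a flat variogram inside the independence envelope is the
#' signal to replace the spatial process with iid cluster effects.
#'
#' @param residuals numeric vector, one value per cluster (typically
#'   cluster-mean residuals from [residuals.geofit()]).
#' @param coords cluster coordinate matrix, km.
#' @param bins number of distance bins, or a vector of break points (km).
#' @param max_dist largest pair distance used (default half the maximum
#'   pairwise distance, the usual rule to avoid sparse far bins).
#' @param envelope number of Monte Carlo permutations of residuals over
#'   locations for a pointwise envelope under spatial independence
#'   (0 = none).
#' @param level envelope coverage.
#' @param seed optional seed for the permutations.
#' @return object of class `"geo_variogram"`: `table` with `mid`
#'   (bin midpoint, km), `gamma` (semivariance; `NA` flagged for empty
#'   bins), `n_pairs`, and optional `lo`/`hi` envelope columns.
#' @export
empirical_variogram <- function(residuals, coords, bins = 12,
                                max_dist = NULL, envelope = 0,
                                level = 0.95, seed = NULL) {
  coords <- as.matrix(coords)
  m <- length(residuals)
  stopifnot(nrow(coords) == m, m >= 2)
  D <- pair_dist(coords)
  iu <- which(upper.tri(D))
  d <- D[iu]
  if (is.null(max_dist)) max_dist <- max(d) / 2
  breaks <- if (length(bins) > 1) bins else
    seq(0, max_dist, length.out = bins + 1)
  sq <- function(r) {
    dif2 <- (outer(r, r, "-")[iu])^2
    keep <- d <= max(breaks) & d >= min(breaks)
    bi <- cut(d[keep], breaks, include.lowest = TRUE, labels = FALSE)
    gam <- tapply(dif2[keep], factor(bi, levels = seq_len(length(breaks) - 1)),
                  function(v) mean(v) / 2)
    as.numeric(gam)
  }
  gamma <- sq(residuals)
  bi_all <- cut(pmin(d, max(breaks)), breaks, include.lowest = TRUE,
                labels = FALSE)
  np <- tabulate(bi_all[d <= max(breaks)], nbins = length(breaks) - 1)
  tab <- data.frame(mid = (utils::head(breaks, -1) + breaks[-1]) / 2,
                    gamma = gamma, n_pairs = np)
  if (envelope > 0) {
    if (!is.null(seed)) set.seed(seed)
    perm <- replicate(envelope, sq(sample(residuals)))
    a <- (1 - level) / 2
    tab$lo <- apply(perm, 1, stats::quantile, probs = a, na.rm = TRUE)
    tab$hi <- apply(perm, 1, stats::quantile, probs = 1 - a, na.rm = TRUE)
  }
  structure(list(table = tab, breaks = breaks, n_perm = envelope,
                 level = level),
            class = "geo_variogram")
}

#' Is there evidence of residual spatial correlation?
#'
#' A variogram is judged flat when every non-empty bin's semivariance lies
#' inside the permutation envelope.
#'
#' @param vg a [empirical_variogram()] result computed with
#'   `envelope > 0`.
#' @return logical: `TRUE` if any bin escapes the envelope.
#' @export
variogram_shows_structure <- function(vg) {
  stopifnot(inherits(vg, "geo_variogram"))
  if (is.null(vg$table$lo))
    stop("variogram was computed without a permutation envelope",
         call. = FALSE)
  ok <- !is.na(vg$table$gamma)
  any(vg$table$gamma[ok] < vg$table$lo[ok] |
        vg$table$gamma[ok] > vg$table$hi[ok])
}

#' @export
print.geo_variogram <- function(x, ...) {
  cat("Empirical semivariogram (", sum(x$table$n_pairs), " pairs in ",
      nrow(x$table), " bins", sep = "")
  if (x$n_perm > 0)
    cat(sprintf("; %d-permutation %.0f%% envelope", x$n_perm,
                100 * x$level))
  cat(")\n")
  print(round(x$table, 4))
  invisible(x)
}

#' @export
plot.geo_variogram <- function(x, xlab = "distance (km)",
                               ylab = "semivariance", ...) {
  tab <- x$table
  graphics::plot(tab$mid, tab$gamma, pch = 19, xlab = xlab, ylab = ylab,
                 ylim = range(c(0, tab$gamma, tab$hi), na.rm = TRUE), ...)
  if (!is.null(tab$lo)) {
    graphics::lines(tab$mid, tab$lo, lty = 2, col = "grey40")
    graphics::lines(tab$mid, tab$hi, lty = 2, col = "grey40")
  }
  invisible(x)
}
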