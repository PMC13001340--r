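#' Sum projection of a z-stack over a fixed-depth window
#'
#' Sums pixel intensities over a window of slices centered on a given
#' slice: the window depth in um is converted to `round(depth / z_step)`
#' slices. The default 1.8-um window matches the quantified projections.
#'
#' @param stack x*y*z integer array.
#' @param z_step_um z-step between slices (um).
#' @param window_um window depth (um).
#' @param center center slice index; defaults to the middle slice.
#' @return 2D integer matrix of summed intensities.
#' @export
sum_projection <- function(stack, z_step_um = 0.3, window_um = 1.8,
                           center = NULL) {
  nz <- dim(stack)[3]
  k <- max(1L, round(window_um / z_step_um))
  if (k > nz) stop("projection window (", k, " slices) exceeds stack depth (",
                   nz, ")")
  if (is.null(center)) center <- (nz + 1) %/% 2
  lo <- center - (k - 1L) %/% 2L
  hi <- lo + k - 1L
  if (lo < 1 || hi > nz) stop("projection window falls outside the stack")
  out <- matrix(0L, nrow = dim(stack)[1], ncol = dim(stack)[2])
  for (z in lo:hi) out <- out + stack[, , z]
  out
}

#' Unit-bin intensity histogram of an image
#'
#' Exact counts of pixels per integer intensity value over a declared
#' range (bin size fixed at 1 intensity unit). Pixels above the range are
#' clipped into the top bin with a warning; all bins are retained.
#'
#' @param image integer matrix (or vector) of non-negative pixel values.
#' @param range length-2 integer `c(lo, hi)` of the histogram range.
#' @param probe,genotype,replicate optional metadata carried on the object.
#' @return object of class `intensity_histogram`: list with `counts`
#'   (named integer vector over `lo:hi`), `range`, `n_pixels`, and the
#'   metadata fields.
#' @export
intensity_histogram <- function(image, range = c(0, 699), probe = NA_character_,
                                genotype = NA_character_,
                                replicate = NA_integer_) {
  px <- as.vector(image)
  if (!length(px)) stop("empty image")
  if (any(px < 0)) stop("negative pixel values")
  lo <- range[1]
  hi <- range[2]
  n_over <- sum(px > hi)
  if (n_over > 0) {
    warning(n_over, " pixel(s) above range clipped into the top bin")
    px <- pmin(px, hi)
  }
  counts <- tabulate(px - lo + 1L, nbins = hi - lo + 1L)
  names(counts) <- lo:hi
  structure(list(counts = counts, range = range, n_pixels = length(px),
                 probe = probe, genotype = genotype, replicate = replicate),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat("intensity_histogram: ", x$n_pixels, " pixels over bins ",
      x$range[1], "-", x$range[2],
      if (!is.na(x$probe)) paste0(" (", x$probe, "/", x$genotype, ")"), "\n",
      sep = "")
  invisible(x)
}

hist_bins <- function(hist) as.numeric(names(hist$counts))

#' Moment-based skewness of an intensity histogram
#'
#' Fisher-Pearson skewness g1 = m3 / m2^(3/2) of the pixel sample implied
#' by the histogram weights, without small-sample bias correction (pixel
#' counts are 1e4-1e6, so the correction is negligible). Identical to the
#' skewness of the raw pixel array.
#'
#' @param hist an `intensity_histogram` (or any list with `counts` named by
#'   bin value).
#' @return skewness (dimensionless).
#' @export
histogram_skewness <- function(hist) {
  x <- hist_bins(hist)
  w <- as.numeric(hist$counts)
  n <- sum(w)
  if (n == 0) stop("empty histogram")
  mu <- sum(w * x) / n
  m2 <- sum(w * (x - mu)^2) / n
  if (m2 == 0) stop("zero-variance histogram (single occupied bin)")
  m3 <- sum(w * (x - mu)^3) / n
  m3 / m2^1.5
}

#' Percentile bin of an intensity histogram
#'
#' The smallest bin value `b` such that the cumulative fraction of pixels
#' at or below `b` reaches `q`/100 (so roughly `q`% of all pixels are less
#' than that value).
#'
#' @param hist an `intensity_histogram`.
#' @param q percentile in (0, 100); default 90.
#' @return the intensity bin value (numeric).
#' @export
percentile_bin <- function(hist, q = 90) {
  if (q <= 0 || q >= 100) stop("q must be in (0, 100)")
  w <- as.numeric(hist$counts)
  n <- sum(w)
  if (n == 0) stop("empty histogram")
  cf <- cumsum(w) / n
  hist_bins(hist)[which(cf >= q / 100)[1]]
}

#' Mean histogram summary
#'
#' @param hist an `intensity_histogram`.
#' @return mean pixel intensity.
#' @export
histogram_mean <- function(hist) {
  w <- as.numeric(hist$counts)
  sum(w * hist_bins(hist)) / sum(w)
}

#' Exact Mann-Whitney U test by null enumeration
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test whose null distribution
#' is obtained by exhaustive enumeration of all `choose(n1+n2, n1)` group
#' assignments of the pooled sample; exact also in the presence of ties
#' (midranks). The two-sided p-value is `min(1, 2 * min(P(U' <= U),
#' P(U' >= U)))`. For pooled sizes above `max_exact` the normal
#' approximation with tie correction is used instead.
#'
#' @param x,y numeric vectors (>= 2 values each for a meaningful test).
#' @param max_exact largest pooled sample size enumerated exactly
#'   (default 16, i.e. up to 8 vs 8).
#' @return list: `U` (statistic for the first sample), `p`, `exact`.
#' @export
#' @examples
#' mann_whitney_exact(1:5, 6:10)$p # 2/252
mann_whitney_exact <- function(x, y, max_exact = 16) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per group")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= max_exact) {
    combs <- utils::combn(n1 + n2, n1)
    Ud <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Ud <= U + eps), mean(Ud >= U - eps)))
    list(U = U, p = p, exact = TRUE)
  } else {
    mu <- n1 * n2 / 2
    tie <- table(pooled)
    sig2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(tie^3 - tie) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- (U - mu) / sqrt(sig2)
    list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
  }
}

#' Compare per-replicate histogram statistics between genotypes
#'
#' For each probe, runs a two-sided exact Mann-Whitney U test of a
#' per-replicate statistic (e.g. skewness or 90th-percentile bin) between
#' two genotypes, then applies Benjamini-Hochberg adjustment across the
#' probes tested together.
#'
#' @param stats_df data.frame with columns `probe`, `genotype`, `replicate`,
#'   `value`.
#' @param group1,group2 the two genotype labels to compare (group1 vs
#'   group2; `delta` is median(group2) - median(group1)).
#' @return data.frame: probe, n1, n2, U, delta, p, padj.
#' @export
compare_genotypes <- function(stats_df, group1, group2) {
  stopifnot(all(c("probe", "genotype", "value") %in% names(stats_df)))
  probes <- unique(stats_df$probe)
  rows <- lapply(probes, function(p) {
    x <- stats_df$value[stats_df$probe == p & stats_df$genotype == group1]
    y <- stats_df$value[stats_df$probe == p & stats_df$genotype == group2]
    if (length(x) < 2 || length(y) < 2) stop("fewer than 2 replicates for ", p)
    mw <- mann_whitney_exact(x, y)
    data.frame(probe = p, n1 = length(x), n2 = length(y), U = mw$U,
               delta = stats::median(y) - stats::median(x), p = mw$p)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Mean log-scale histogram curve across replicates
#'
#' Per-bin mean count and standard error across replicate histograms, with
#' a log10(mean + 1) curve for plotting (a pseudocount handles empty high
#' bins) and the group-mean 90th-percentile bin as a vertical marker.
#'
#' @param hists list of `intensity_histogram`s from one genotype; all must
#'   share the same range.
#' @return data.frame (bin, mean, sem, log10_mean) with attribute
#'   `mean_p90` (mean of per-replicate 90th-percentile bins).
#' @export
mean_log_histogram <- function(hists) {
  if (!length(hists)) stop("no histograms")
  rngs <- vapply(hists, function(h) h$range, numeric(2))
  if (any(rngs[1, ] != rngs[1, 1]) || any(rngs[2, ] != rngs[2, 1])) {
    stop("mismatched histogram ranges")
  }
  cm <- vapply(hists, function(h) as.numeric(h$counts),
               numeric(length(hists[[1]]$counts)))
  mu <- rowMeans(cm)
  sem <- if (length(hists) > 1) {
    apply(cm, 1, stats::sd) / sqrt(length(hists))
  } else {
    rep(0, length(mu))
  }
  out <- data.frame(bin = hist_bins(hists[[1]]), mean = mu, sem = sem,
                    log10_mean = log10(mu + 1))
  attr(out, "mean_p90") <- mean(vapply(hists, percentile_bin, numeric(1)))
  out
}
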