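#' Genome-wide repeat-unit-sized bin scan
#'
#' Tiles every chromosome with non-overlapping bins of `bin_len` bp anchored
#' at coordinate 0, sums the track signal within each bin (track bin value x
#' covered bases, so the sum is total per-base signal mass), and ranks bins
#' by descending sum. A trailing partial bin is retained and flagged.
#' Bins overlapping any masked (`NA`) track bin are flagged masked and
#' excluded from ranking. Ties share the minimum rank.
#'
#' @param track a `coverage_track` in HGC state (use `allow_state` to relax).
#' @param bin_len scan bin length in bp; default 5080, the histone
#'   repeat-unit size, so the consensus chromosome is exactly one bin.
#' @param allow_state normalization states accepted (default `"HGC"`).
#' @return data.frame of class `bin_scan_table`: chrom, start, end (0-based
#'   half-open), signal, rank (NA for masked), masked, partial.
#' @export
bin_scan <- function(track, bin_len = 5080, allow_state = "HGC") {
  stopifnot(inherits(track, "coverage_track"))
  if (!track$state %in% allow_state) {
    stop("track state '", track$state, "' not in: ",
         paste(allow_state, collapse = ", "))
  }
  bs <- track$bin_size
  if (bin_len < bs) stop("bin_len smaller than track bin size")
  rows <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    n <- track$chrom_lengths[[ch]]
    if (!length(v)) return(NULL)
    # base-mass of each track bin (trailing track bin may be short)
    tb_start <- (seq_along(v) - 1) * bs
    tb_end <- pmin(tb_start + bs, n)
    nbin <- ceiling(n / bin_len)
    sums <- numeric(nbin)
    masked <- logical(nbin)
    # a track bin can straddle at most one scan-bin boundary (bin_len >= bs)
    i1 <- tb_start %/% bin_len
    boundary <- (i1 + 1) * bin_len
    w1 <- pmin(tb_end, boundary) - tb_start
    w2 <- tb_end - pmin(tb_end, boundary)
    vv <- v
    isna <- is.na(vv)
    vv[isna] <- 0
    m1 <- vv * w1
    sums <- as.numeric(tapply(m1, factor(i1, levels = 0:(nbin - 1)), sum,
                              default = 0))
    if (any(w2 > 0)) {
      sel <- w2 > 0
      i2 <- i1[sel] + 1
      add <- tapply(vv[sel] * w2[sel], factor(i2, levels = 0:(nbin - 1)), sum,
                    default = 0)
      sums <- sums + as.numeric(add)
    }
    if (any(isna)) {
      mi <- unique(c(i1[isna], i1[isna & w2 > 0] + 1))
      masked[mi + 1] <- TRUE
    }
    starts <- (seq_len(nbin) - 1) * bin_len
    ends <- pmin(starts + bin_len, n)
    data.frame(chrom = ch, start = starts, end = ends, signal = sums,
               masked = masked, partial = (ends - starts) < bin_len)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$rank <- NA_integer_
  ok <- !out$masked
  out$rank[ok] <- rank(-out$signal[ok], ties.method = "min")
  class(out) <- c("bin_scan_table", "data.frame")
  attr(out, "bin_len") <- bin_len
  attr(out, "chrom_order") <- names(track$values)
  out
}

#' Manhattan-style plot table from a bin scan
#'
#' Lays bins out on a single cumulative genome coordinate in deterministic
#' chromosome order (assembly order with the consensus chromosome last, so
#' it appears at the far right) and labels the top-`k` bins by signal.
#'
#' @param scan a `bin_scan_table` from [bin_scan()].
#' @param consensus_name consensus chromosome placed last (ignored when
#'   absent).
#' @param top_k number of top bins to label.
#' @return data.frame: chrom, start, end, signal, rank, cum_pos (bp),
#'   label (bin name for the top-k, otherwise NA).
#' @export
manhattan_table <- function(scan, consensus_name = "chrHis", top_k = 5) {
  stopifnot(inherits(scan, "bin_scan_table"))
  if (!nrow(scan)) stop("empty scan")
  ord <- attr(scan, "chrom_order")
  if (is.null(ord)) ord <- unique(scan$chrom)
  if (consensus_name %in% ord) {
    ord <- c(setdiff(ord, consensus_name), consensus_name)
  }
  chr_len <- vapply(ord, function(ch) max(scan$end[scan$chrom == ch]),
                    numeric(1))
  offs <- stats::setNames(c(0, cumsum(chr_len))[seq_along(ord)], ord)
  out <- scan[order(match(scan$chrom, ord), scan$start), , drop = FALSE]
  out$cum_pos <- offs[out$chrom] + out$start
  out$label <- NA_character_
  lab <- which(!out$masked & out$rank <= top_k)
  out$label[lab] <- sprintf("%s:%d-%d", out$chrom[lab], out$start[lab],
                            out$end[lab])
  rownames(out) <- NULL
  out
}

#' Scaled gene-body signal matrix
#'
#' Builds a per-gene signal matrix in the scale-regions style: `flank` bp
#' upstream of the TSS, the gene body linearly rescaled to `body` bp, and
#' `flank` bp downstream of the TES, aggregated into fixed-width columns by
#' mean per-base signal. Minus-strand genes are oriented TSS-left (their
#' rows reversed). Rows are sorted in descending order of total signal.
#' Column means use exact fractional-base integration of the
#' piecewise-constant track, so a constant track gives exactly constant
#' rows irrespective of gene length.
#'
#' @param track a `coverage_track` (HGC state expected for occupancy use,
#'   but any state works).
#' @param genes data.frame: chrom, start, end (0-based half-open),
#'   strand ("+"/"-"), name.
#' @param body scaled body length in bp (default 2000).
#' @param flank flank length in bp (default 500).
#' @param col_width column width in bp (default 10, giving 50 + 200 + 50
#'   columns).
#' @return numeric matrix of class `gene_signal_matrix`, rows named by
#'   gene, with attributes `totals` (per-row total signal, row order) and
#'   `n_flank_cols`/`n_body_cols`. Masked (`NA`) track bins propagate NA
#'   into overlapping columns.
#' @export
gene_matrix <- function(track, genes, body = 2000, flank = 500,
                        col_width = 10) {
  stopifnot(inherits(track, "coverage_track"),
            all(c("chrom", "start", "end", "strand", "name") %in% names(genes)),
            body %% col_width == 0, flank %% col_width == 0)
  nf <- flank / col_width
  nb <- body / col_width
  ncol_out <- nf + nb + nf
  bs <- track$bin_size
  unknown <- setdiff(unique(genes$chrom), names(track$values))
  if (length(unknown)) stop("gene on unknown chromosome(s)")
  if (any(genes$start < 0 | genes$end > track$chrom_lengths[genes$chrom])) {
    stop("gene outside chromosome bounds")
  }

  # mean of the piecewise-constant per-base signal over real interval [a, b)
  seg_mean <- function(cum, a, b, n_bases) {
    a <- max(a, 0); b <- min(b, n_bases)
    if (b <= a) return(NA_real_)
    interp <- function(x) {
      i <- floor(x / bs)
      lo <- cum[i + 1]
      hi <- cum[min(i + 2, length(cum))]
      bw <- min((i + 1) * bs, n_bases) - i * bs # trailing bin may be short
      frac <- if (bw > 0) (x - i * bs) / bw else 0
      lo + (hi - lo) * frac
    }
    (interp(b) - interp(a)) / (b - a)
  }

  mat <- matrix(NA_real_, nrow = nrow(genes), ncol = ncol_out,
                dimnames = list(genes$name, NULL))
  for (g in seq_len(nrow(genes))) {
    ch <- genes$chrom[g]
    v <- track$values[[ch]]
    n <- track$chrom_lengths[[ch]]
    # cumulative base-mass at track-bin edges; NA poisons overlapped columns
    mass <- v * (pmin((seq_along(v)) * bs, n) - (seq_along(v) - 1) * bs)
    cum <- c(0, cumsum(mass))
    gs <- genes$start[g]
    ge <- genes$end[g]
    glen <- ge - gs
    row <- numeric(ncol_out)
    # upstream flank columns (genomic orientation)
    for (j in seq_len(nf)) {
      row[j] <- seg_mean(cum, gs - flank + (j - 1) * col_width,
                         gs - flank + j * col_width, n)
    }
    for (j in seq_len(nb)) {
      a <- gs + glen * (j - 1) / nb
      b <- gs + glen * j / nb
      row[nf + j] <- seg_mean(cum, a, b, n)
    }
    for (j in seq_len(nf)) {
      row[nf + nb + j] <- seg_mean(cum, ge + (j - 1) * col_width,
                                   ge + j * col_width, n)
    }
    if (genes$strand[g] == "-") row <- rev(row)
    mat[g, ] <- row
  }
  totals <- rowSums(mat, na.rm = TRUE)
  ord <- order(-totals)
  mat <- mat[ord, , drop = FALSE]
  structure(mat, totals = totals[ord], n_flank_cols = nf, n_body_cols = nb,
            class = c("gene_signal_matrix", class(mat)))
}

#' Hierarchically cluster the rows of a gene signal matrix
#'
#' Agglomerative hierarchical clustering of row vectors with Ward linkage
#' (`ward.D2`) on Euclidean distance, cut at `k` clusters. Deterministic for
#' fixed input; permuting rows permutes labels identically (the partition is
#' row-order invariant, though label numbers follow dendrogram order).
#'
#' @param mat numeric matrix (e.g. a `gene_signal_matrix`); `NA` entries are
#'   replaced by 0 for distance computation.
#' @param k number of clusters (default 3).
#' @return integer cluster labels named by row.
#' @export
cluster_rows <- function(mat, k = 3) {
  stopifnot(k >= 1, k <= nrow(mat))
  m <- as.matrix(mat)
  m[is.na(m)] <- 0
  if (k == nrow(m)) {
    return(stats::setNames(seq_len(nrow(m)), rownames(m)))
  }
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Merge per-gene occupancy signal with a differential-expression table
#'
#' Inner-joins summed per-gene signal with an external DE table on gene
#' identifier, reports unmatched genes on both sides, and sorts by signal
#' (descending). The result is the MA-style table relating occupancy to
#' expression change.
#'
#' @param signal data.frame (gene, signal), e.g. from a
#'   `gene_signal_matrix`'s row totals.
#' @param de data.frame with columns gene, log2fc, padj (extra columns
#'   carried through).
#' @return data.frame (gene, signal, log2fc, padj, ...) sorted by signal.
#' @export
merge_signal_with_de <- function(signal, de) {
  stopifnot(all(c("gene", "signal") %in% names(signal)),
            all(c("gene", "log2fc") %in% names(de)))
  common <- intersect(signal$gene, de$gene)
  if (!length(common)) {
    stop("no overlapping genes (signal side: ", nrow(signal),
         ", DE side: ", nrow(de), ")")
  }
  only_sig <- setdiff(signal$gene, de$gene)
  only_de <- setdiff(de$gene, signal$gene)
  if (length(only_sig) || length(only_de)) {
    message(length(only_sig), " gene(s) with signal but no DE entry; ",
            length(only_de), " DE gene(s) without signal")
  }
  out <- merge(signal, de, by = "gene")
  out <- out[order(-out$signal), , drop = FALSE]
  rownames(out) <- NULL
  out
}
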