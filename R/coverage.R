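#' Coverage tracks with CPM and per-gene-copy (HGC) normalization
#'
#' A `coverage_track` stores, per chromosome, mean per-base fragment depth
#' in fixed-size bins, together with its normalization state. States move
#' strictly `raw -> CPM -> HGC`:
#' * raw: mean per-base depth per bin (fragment pileup);
#' * CPM: raw x 1e6 / total mapped fragments (counts per million);
#' * HGC: CPM with the consensus chromosome additionally divided by the
#'   array copy number, so multi-copy signal is comparable to single-copy
#'   loci ("per histone gene copy").
#'
#' @name coverage_track
NULL

new_coverage_track <- function(values, bin_size, state, chrom_lengths,
                               total_fragments = NA_real_) {
  structure(list(values = values, bin_size = bin_size, state = state,
                 chrom_lengths = chrom_lengths,
                 total_fragments = total_fragments),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track [", x$state, "]: ", length(x$values),
      " chromosomes, bin size ", x$bin_size, " bp\n", sep = "")
  invisible(x)
}

#' Compute binned fragment coverage
#'
#' Piles up fragments (weighted) into per-base depth via run-length
#' encoding and averages the depth within fixed-size bins. The value of a
#' bin is the *mean* per-base depth over the bases it covers (coverage-track
#' convention); a trailing partial bin is averaged over its actual width.
#'
#' @param frags data.frame (chrom, start, end) 0-based half-open; optional
#'   `weight` column.
#' @param chrom_lengths named vector of chromosome lengths, or a
#'   `collapsed_assembly`.
#' @param bin_size bin width in bp (default 2, matching fine-grained CPM
#'   signal tracks).
#' @return a `coverage_track` in state `"raw"` whose `total_fragments` is
#'   the number of input rows (callers projecting wrapped fragments should
#'   override via [to_cpm()]'s `total`).
#' @export
compute_coverage <- function(frags, chrom_lengths, bin_size = 2) {
  if (inherits(chrom_lengths, "collapsed_assembly")) {
    chrom_lengths <- chrom_lengths$chrom_lengths
  }
  stopifnot(bin_size >= 1)
  unknown <- setdiff(unique(frags$chrom), names(chrom_lengths))
  if (length(unknown)) {
    stop("fragments on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  if (nrow(frags) &&
      any(frags$start < 0 |
          frags$end > chrom_lengths[frags$chrom])) {
    stop("fragment outside chromosome bounds")
  }
  w <- if ("weight" %in% names(frags)) frags$weight else rep(1, nrow(frags))
  values <- lapply(names(chrom_lengths), function(ch) {
    n <- chrom_lengths[[ch]]
    sel <- frags$chrom == ch
    nb <- ceiling(n / bin_size)
    if (!any(sel)) return(numeric(nb))
    ir <- IRanges::IRanges(start = frags$start[sel] + 1, end = frags$end[sel])
    cov <- IRanges::coverage(ir, weight = w[sel], width = n)
    bs <- seq(1, n, by = bin_size)
    be <- pmin(bs + bin_size - 1, n)
    v <- IRanges::viewSums(IRanges::Views(cov, start = bs, end = be))
    as.numeric(v) / (be - bs + 1)
  })
  names(values) <- names(chrom_lengths)
  new_coverage_track(values, bin_size, "raw", chrom_lengths,
                     total_fragments = nrow(frags))
}

#' CPM-normalize a raw coverage track
#'
#' Multiplies every bin by `1e6 / total` where `total` is the number of
#' mapped fragments (counts-per-million-mapped-fragments, the paired-end
#' coverage-tool convention: a fragment counts once however many pieces it
#' was projected in).
#'
#' @param track a raw `coverage_track`.
#' @param total total mapped fragment count; defaults to the count recorded
#'   at pileup time.
#' @return the track in state `"CPM"`.
#' @export
to_cpm <- function(track, total = track$total_fragments) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$state != "raw") stop("to_cpm requires a raw track")
  if (is.na(total) || total <= 0) stop("total fragments must be > 0")
  track$values <- lapply(track$values, function(v) v * 1e6 / total)
  track$state <- "CPM"
  track$total_fragments <- total
  track
}

#' Apply per-gene-copy (HGC) normalization to the consensus chromosome
#'
#' Divides all CPM signal on the consensus chromosome by the tandem-array
#' copy number, yielding per-gene-copy signal directly comparable in scale
#' to single-copy genomic regions. All other chromosomes are untouched.
#' (Also written "HCG" in some sources; this package standardizes on HGC.)
#'
#' @param track a CPM `coverage_track`.
#' @param consensus_name consensus chromosome name.
#' @param copy_number array copy number C (default 100).
#' @return the track in state `"HGC"`.
#' @export
apply_hgc <- function(track, consensus_name = "chrHis", copy_number = 100) {
  stopifnot(inherits(track, "coverage_track"), copy_number >= 1)
  if (track$state != "CPM") stop("apply_hgc requires a CPM track")
  if (!consensus_name %in% names(track$values)) {
    stop("consensus chromosome '", consensus_name, "' absent from track")
  }
  track$values[[consensus_name]] <- track$values[[consensus_name]] / copy_number
  track$state <- "HGC"
  track
}

#' Mask blacklisted regions in a coverage track
#'
#' Sets every bin overlapping any blacklist interval to `NA`; masked bins
#' are excluded from all downstream sums and rankings. Masking uses an
#' any-overlap rule at bin resolution (a bin partially covered by a
#' blacklist interval is wholly masked — conservative exclusion).
#'
#' @param track a `coverage_track` (any state).
#' @param blacklist data.frame (chrom, start, end), 0-based half-open, or a
#'   `GRanges`.
#' @return the track with masked bins set to `NA`.
#' @export
mask_blacklist <- function(track, blacklist) {
  stopifnot(inherits(track, "coverage_track"))
  if (methods::is(blacklist, "GRanges")) {
    blacklist <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(blacklist)),
      start = GenomicRanges::start(blacklist) - 1,
      end = GenomicRanges::end(blacklist))
  }
  if (nrow(blacklist) == 0) return(track)
  stopifnot(all(c("chrom", "start", "end") %in% names(blacklist)))
  if (any(blacklist$end <= blacklist$start)) stop("malformed blacklist interval")
  unknown <- setdiff(unique(blacklist$chrom), names(track$values))
  if (length(unknown)) stop("blacklist on unknown chromosome(s)")
  bs <- track$bin_size
  for (i in seq_len(nrow(blacklist))) {
    ch <- blacklist$chrom[i]
    first <- floor(blacklist$start[i] / bs) + 1
    last <- ceiling(blacklist$end[i] / bs)
    last <- min(last, length(track$values[[ch]]))
    if (first <= last) track$values[[ch]][first:last] <- NA_real_
  }
  track
}

#' Write a coverage track as bedGraph
#'
#' Emits a 4-column bedGraph (0-based half-open), one line per run of
#' constant value; `NA` (masked) bins are omitted.
#'
#' @param track a `coverage_track`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- c(0, ends_bin[-length(ends_bin)])
    keep <- !is.na(r$values)
    if (!any(keep)) next
    starts <- starts_bin[keep] * bs
    ends <- pmin(ends_bin[keep] * bs, track$chrom_lengths[[ch]])
    writeLines(sprintf("%s\t%d\t%d\t%g", ch, as.integer(starts),
                       as.integer(ends), r$values[keep]), con)
  }
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param bin_size bin size of the stored track.
#' @param state normalization state to stamp on the result.
#' @return a `coverage_track`.
#' @export
read_bedgraph <- function(path, chrom_lengths, bin_size, state = "raw") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  values <- lapply(names(chrom_lengths), function(ch) {
    nb <- ceiling(chrom_lengths[[ch]] / bin_size)
    v <- numeric(nb)
    sel <- as.character(GenomicRanges::seqnames(gr)) == ch
    if (any(sel)) {
      s0 <- GenomicRanges::start(gr[sel]) - 1
      e0 <- GenomicRanges::end(gr[sel])
      sc <- GenomicRanges::mcols(gr[sel])$score
      for (i in seq_along(s0)) {
        v[(s0[i] %/% bin_size + 1):(((e0[i] - 1) %/% bin_size) + 1)] <- sc[i]
      }
    }
    v
  })
  names(values) <- names(chrom_lengths)
  new_coverage_track(values, bin_size, state, chrom_lengths)
}
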