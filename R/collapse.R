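#' Build a collapsed-repeat reference assembly
#'
#' Removes the tandem-array interval from its chromosome and appends a new
#' chromosome carrying exactly one copy of the repeat unit, mirroring the
#' custom assembly strategy used to map multi-copy histone-array reads: the
#' partially assembled locus is excised and replaced by a single consensus
#' repeat unit as its own chromosome. Coordinates printed in genome-browser
#' dialect are 1-based inclusive; the conversion to the package's internal
#' 0-based half-open convention happens here, at the I/O boundary.
#'
#' @param chrom_lengths named vector of chromosome lengths of the source
#'   genome (bp), or a [Biostrings::DNAStringSet] (lengths and sequence are
#'   then both used).
#' @param array_chrom chromosome carrying the array.
#' @param excise_start,excise_end 1-based inclusive interval to excise.
#' @param unit_seq DNA sequence of the consensus unit (character or
#'   `DNAString`); required when emitting FASTA, otherwise only its length
#'   matters and `unit_length` may be given instead.
#' @param unit_length length of the consensus unit; inferred from
#'   `unit_seq` when omitted.
#' @param copy_number tandem copy number C recorded in the assembly. An
#'   independent parameter: never inferred from the excised span, which for
#'   an under-assembled locus is much shorter than C x L.
#' @param consensus_name name of the appended consensus chromosome.
#' @return an object of class `collapsed_assembly`: list with
#'   `chrom_lengths` (post-excision, consensus last), `consensus_name`,
#'   `unit_length`, `copy_number`, `array_chrom`, `excised` (1-based
#'   inclusive start/end), `excised_span`, `shift` (bp subtracted from
#'   coordinates downstream of the excision) and optionally `genome`
#'   (DNAStringSet of the collapsed assembly).
#' @export
#' @examples
#' asm <- build_collapsed_reference(c(chr1 = 10000), "chr1", 2001, 7000,
#'                                  unit_length = 500, copy_number = 10)
#' asm$chrom_lengths # chr1 5000, chrHis 500
build_collapsed_reference <- function(chrom_lengths, array_chrom,
                                      excise_start, excise_end,
                                      unit_seq = NULL, unit_length = NULL,
                                      copy_number = 100,
                                      consensus_name = "chrHis") {
  genome <- NULL
  if (methods::is(chrom_lengths, "DNAStringSet")) {
    genome <- chrom_lengths
    chrom_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
  }
  stopifnot(!is.null(names(chrom_lengths)), array_chrom %in% names(chrom_lengths),
            copy_number >= 1)
  if (is.null(unit_length)) {
    if (is.null(unit_seq)) stop("give unit_seq or unit_length")
    unit_length <- nchar(as.character(unit_seq))
  }
  if (!is.null(unit_seq) && nchar(as.character(unit_seq)) == 0) {
    stop("empty unit sequence")
  }
  if (excise_start < 1 || excise_end > chrom_lengths[[array_chrom]] ||
      excise_end < excise_start) {
    stop("excision interval outside chromosome")
  }
  span <- excise_end - excise_start + 1
  lens <- chrom_lengths
  lens[[array_chrom]] <- lens[[array_chrom]] - span
  lens <- c(lens, stats::setNames(as.numeric(unit_length), consensus_name))
  out_genome <- NULL
  if (!is.null(genome)) {
    if (is.null(unit_seq)) stop("unit_seq required to emit sequence")
    src <- as.character(genome[[array_chrom]])
    collapsed <- paste0(substr(src, 1, excise_start - 1),
                        substr(src, excise_end + 1, nchar(src)))
    out <- as.character(genome)
    out[[array_chrom]] <- collapsed
    out <- c(out, stats::setNames(as.character(unit_seq), consensus_name))
    out_genome <- Biostrings::DNAStringSet(out)
  }
  structure(
    list(chrom_lengths = lens, consensus_name = consensus_name,
         unit_length = as.numeric(unit_length),
         copy_number = as.numeric(copy_number),
         array_chrom = array_chrom,
         excised = c(start = as.numeric(excise_start), end = as.numeric(excise_end)),
         excised_span = as.numeric(span), shift = as.numeric(span),
         genome = out_genome),
    class = "collapsed_assembly"
  )
}

#' @export
print.collapsed_assembly <- function(x, ...) {
  cat("collapsed_assembly:", length(x$chrom_lengths), "chromosomes;",
      "consensus", x$consensus_name, sprintf("(%d bp x %d copies);",
      as.integer(x$unit_length), as.integer(x$copy_number)),
      "excised", x$array_chrom, sprintf("%s-%s (%d bp)\n",
      format(x$excised["start"], big.mark = ","),
      format(x$excised["end"], big.mark = ","), as.integer(x$excised_span)))
  invisible(x)
}

#' Project fragments from expanded-array coordinates onto the collapsed assembly
#'
#' Deterministic surrogate for what alignment to the collapsed assembly does
#' implicitly. Fragments wholly inside the array map to the consensus
#' chromosome at offset `(position - array_start) mod L`; fragments spanning
#' a copy junction wrap across the consensus end/start (the tandem repeat is
#' head-to-tail, so the consensus behaves circularly) and are emitted as two
#' pieces flagged `wrapped`; fragments downstream of the array shift left by
#' the excised span; fragments upstream are unchanged; fragments straddling
#' the array's outer boundary have no unambiguous collapsed location and are
#' dropped and counted.
#'
#' @param frags data.frame (chrom, start, end), 0-based half-open, in
#'   *expanded* coordinates; an optional `weight` column is carried through.
#' @param array list describing the expanded array (as returned in
#'   `simulate_genome()$array`): chrom, start0, end0, unit_length.
#' @param consensus_name name of the consensus chromosome in the output.
#' @param wrap if `FALSE`, junction-spanning fragments are dropped (and
#'   counted) instead of wrapped.
#' @return data.frame (chrom, start, end, weight, wrapped) with attributes
#'   `n_dropped_boundary` (fragments straddling the array's outer edges) and
#'   `n_dropped_junction` (only when `wrap = FALSE`, or longer than the
#'   unit).
#' @export
project_fragments <- function(frags, array, consensus_name = "chrHis",
                              wrap = TRUE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(frags)))
  w <- if ("weight" %in% names(frags)) frags$weight else rep(1, nrow(frags))
  a0 <- array$start0
  a1 <- array$end0
  L <- array$unit_length
  shift <- a1 - a0 # entire expanded array is excised from the chromosome
  on_arr_chr <- frags$chrom == array$chrom
  s <- frags$start
  e <- frags$end
  if (any(e <= s)) stop("malformed fragment (end <= start)")
  upstream <- on_arr_chr & e <= a0
  downstream <- on_arr_chr & s >= a1
  inside <- on_arr_chr & s >= a0 & e <= a1
  boundary <- on_arr_chr & !upstream & !downstream & !inside
  other <- !on_arr_chr

  keep_idx <- which(other | upstream)
  out_chrom <- frags$chrom[keep_idx]
  out_s <- s[keep_idx]
  out_e <- e[keep_idx]
  out_w <- w[keep_idx]
  out_wr <- rep(FALSE, length(keep_idx))

  di <- which(downstream)
  if (length(di)) {
    out_chrom <- c(out_chrom, frags$chrom[di])
    out_s <- c(out_s, s[di] - shift)
    out_e <- c(out_e, e[di] - shift)
    out_w <- c(out_w, w[di])
    out_wr <- c(out_wr, rep(FALSE, length(di)))
  }

  n_drop_junction <- 0
  ii <- which(inside)
  if (length(ii)) {
    off <- (s[ii] - a0) %% L
    len <- e[ii] - s[ii]
    too_long <- len > L
    n_drop_junction <- n_drop_junction + sum(too_long)
    plain <- !too_long & (off + len <= L)
    wrapping <- !too_long & !plain
    if (any(plain)) {
      out_chrom <- c(out_chrom, rep(consensus_name, sum(plain)))
      out_s <- c(out_s, off[plain])
      out_e <- c(out_e, off[plain] + len[plain])
      out_w <- c(out_w, w[ii][plain])
      out_wr <- c(out_wr, rep(FALSE, sum(plain)))
    }
    if (any(wrapping)) {
      if (wrap) {
        nw <- sum(wrapping)
        out_chrom <- c(out_chrom, rep(consensus_name, 2 * nw))
        out_s <- c(out_s, off[wrapping], rep(0, nw))
        out_e <- c(out_e, rep(L, nw), off[wrapping] + len[wrapping] - L)
        out_w <- c(out_w, rep(w[ii][wrapping], 2))
        out_wr <- c(out_wr, rep(TRUE, 2 * nw))
      } else {
        n_drop_junction <- n_drop_junction + sum(wrapping)
      }
    }
  }
  out <- data.frame(chrom = out_chrom, start = out_s, end = out_e,
                    weight = out_w, wrapped = out_wr)
  rownames(out) <- NULL
  attr(out, "n_dropped_boundary") <- sum(boundary)
  attr(out, "n_dropped_junction") <- n_drop_junction
  out
}
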