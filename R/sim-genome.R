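#' Specification of a genome carrying one tandem gene array
#'
#' Describes a genome in which one chromosome carries a head-to-tail tandem
#' array of `copy_number` copies of a repeat unit of length `unit_length`.
#' Defaults mirror the Drosophila replication-dependent histone locus: a
#' 5080-bp repeat unit present in roughly 100 tandem copies. The native
#' locus is only partially assembled in reference genomes, so the simulated
#' "expanded" array (copy_number x unit_length bp) is an idealization of the
#' true array rather than a copy of any reference interval.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#'   These are the lengths of the *expanded* genome outside the array; the
#'   array chromosome's final length is its stated length minus the
#'   replaced interval plus `copy_number * unit_length`.
#' @param array_chrom name of the chromosome carrying the array.
#' @param array_start 1-based start of the interval replaced by the array.
#' @param array_end 1-based inclusive end of the replaced interval. Defaults
#'   to `array_start + copy_number * unit_length - 1` so the chromosome
#'   length is preserved.
#' @param unit_length repeat-unit length L in bp.
#' @param copy_number number of tandem copies C.
#' @param unit_seq optional DNA string of length `unit_length`; random if
#'   omitted (generated at [simulate_genome()] time from its seed).
#' @return an object of class `sim_genome_spec`.
#' @export
sim_genome_spec <- function(chrom_lengths = c(chrA = 1e6, chrB = 1e6, chrC = 1e6),
                            array_chrom = "chrB",
                            array_start = 400001,
                            array_end = NULL,
                            unit_length = 5080,
                            copy_number = 100,
                            unit_seq = NULL) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            array_chrom %in% names(chrom_lengths),
            unit_length >= 1, copy_number >= 1, array_start >= 1)
  if (is.null(array_end)) {
    array_end <- array_start + copy_number * unit_length - 1
  }
  if (array_end < array_start) stop("array_end < array_start")
  if (!is.null(unit_seq)) {
    unit_seq <- as.character(unit_seq)
    if (nchar(unit_seq) != unit_length) {
      stop("unit_seq length (", nchar(unit_seq), ") != unit_length (",
           unit_length, ")")
    }
  }
  structure(
    list(chrom_lengths = chrom_lengths, array_chrom = array_chrom,
         array_start = as.numeric(array_start), array_end = as.numeric(array_end),
         unit_length = as.numeric(unit_length),
         copy_number = as.numeric(copy_number), unit_seq = unit_seq),
    class = "sim_genome_spec"
  )
}

#' Simulate a genome with an expanded tandem array
#'
#' Builds the "expanded" genome in which the interval
#' `[array_start, array_end]` of the array chromosome is replaced by exactly
#' `copy_number` head-to-tail copies of the repeat unit. The returned
#' annotation records the true copy boundaries in expanded coordinates
#' (0-based half-open, the package's internal convention).
#'
#' @param spec a [sim_genome_spec()].
#' @param seed integer seed used to draw random sequence (background and,
#'   if unspecified, the unit).
#' @param strict if `TRUE`, error when the replaced interval's length does
#'   not equal `copy_number * unit_length` (i.e. replacement would change
#'   the chromosome length).
#' @param sequences if `FALSE`, skip sequence generation and return only
#'   lengths and annotation (fast path for fragment simulation).
#' @return list with elements `genome` (a [Biostrings::DNAStringSet], or
#'   `NULL` when `sequences = FALSE`), `chrom_lengths` (expanded lengths),
#'   `array` (list: chrom, start0, end0, unit_length, copy_number,
#'   copy_starts0) and `spec`.
#' @export
simulate_genome <- function(spec, seed = 1L, strict = FALSE, sequences = TRUE) {
  stopifnot(inherits(spec, "sim_genome_spec"))
  L <- spec$unit_length
  C <- spec$copy_number
  span_in <- spec$array_end - spec$array_start + 1
  if (strict && span_in != C * L) {
    stop("replaced interval length (", span_in, ") != copy_number * unit_length (",
         C * L, ")")
  }
  if (spec$array_end > spec$chrom_lengths[[spec$array_chrom]]) {
    stop("array interval extends beyond its chromosome")
  }
  lens <- spec$chrom_lengths
  lens[[spec$array_chrom]] <- lens[[spec$array_chrom]] - span_in + C * L
  arr_start0 <- spec$array_start - 1
  arr_end0 <- arr_start0 + C * L
  genome <- NULL
  unit <- spec$unit_seq
  if (sequences) {
    built <- with_seed(derive_seed(seed, "genome"), {
      if (is.null(unit)) {
        unit <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                      collapse = "")
      }
      seqs <- vapply(names(lens), function(ch) {
        n <- lens[[ch]]
        if (ch == spec$array_chrom) {
          pre <- paste(sample(c("A", "C", "G", "T"), arr_start0, replace = TRUE),
                       collapse = "")
          post_n <- n - arr_end0
          post <- paste(sample(c("A", "C", "G", "T"), post_n, replace = TRUE),
                        collapse = "")
          paste0(pre, strrep(unit, C), post)
        } else {
          paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
        }
      }, character(1))
      list(seqs = seqs, unit = unit)
    })
    unit <- built$unit
    genome <- Biostrings::DNAStringSet(built$seqs)
    names(genome) <- names(lens)
  }
  list(
    genome = genome,
    chrom_lengths = lens,
    array = list(chrom = spec$array_chrom, start0 = arr_start0, end0 = arr_end0,
                 unit_length = L, copy_number = C,
                 copy_starts0 = arr_start0 + L * (seq_len(C) - 1),
                 unit_seq = unit),
    spec = spec
  )
}

#' Parameters for fragment simulation
#'
#' Fragment start positions are drawn with per-bp weight equal to the
#' background rate everywhere, multiplied by `enrichment` inside the tandem
#' array and by each peak's fold inside optional off-target peaks. Fragment
#' lengths follow a truncated normal; the default Normal(150, 30) clipped to
#' [50, 700] matches typical short paired-end chromatin-profiling inserts
#' with a 700-bp upper alignment bound.
#'
#' @param n_fragments total fragment count N.
#' @param enrichment per-copy enrichment factor E (fold over background).
#' @param frag_mean,frag_sd,frag_min,frag_max fragment length distribution.
#' @param background_rate uniform per-bp sampling weight.
#' @param peaks optional data.frame (chrom, start, end, fold), 0-based
#'   half-open, for off-target peaks.
#' @return an object of class `fragment_sim_params`.
#' @export
fragment_sim_params <- function(n_fragments = 1e6, enrichment = 1,
                                frag_mean = 150, frag_sd = 30,
                                frag_min = 50, frag_max = 700,
                                background_rate = 1, peaks = NULL) {
  stopifnot(n_fragments >= 0, enrichment >= 0, frag_min >= 1,
            frag_max >= frag_min, background_rate > 0)
  if (!is.null(peaks)) {
    stopifnot(all(c("chrom", "start", "end", "fold") %in% names(peaks)))
  }
  structure(
    list(n_fragments = as.numeric(n_fragments), enrichment = enrichment,
         frag_mean = frag_mean, frag_sd = frag_sd, frag_min = frag_min,
         frag_max = frag_max, background_rate = background_rate, peaks = peaks),
    class = "fragment_sim_params"
  )
}

#' Simulate aligned fragments over an expanded genome
#'
#' Samples `n_fragments` fragments whose start positions follow the weighted
#' per-bp density described in [fragment_sim_params()] and whose lengths are
#' truncated-normal. Sampling is exact two-stage multinomial: a region
#' (constant-weight segment) is chosen with probability proportional to
#' length x weight, then a uniform start within it. Fragments are clipped at
#' the chromosome end.
#'
#' @param sim a genome from [simulate_genome()].
#' @param params a [fragment_sim_params()].
#' @param seed integer seed; identical seeds give identical fragment sets.
#' @return data.frame (chrom, start, end), 0-based half-open.
#' @export
simulate_fragments <- function(sim, params, seed = 1L) {
  stopifnot(inherits(params, "fragment_sim_params"))
  if (params$enrichment < 0) stop("negative enrichment")
  n <- params$n_fragments
  if (n == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  lens <- sim$chrom_lengths
  # Build constant-weight segments: background everywhere, the array
  # interval at background x E, peaks at background x fold.
  segs <- do.call(rbind, lapply(names(lens), function(ch) {
    data.frame(chrom = ch, start = 0, end = lens[[ch]],
               w = params$background_rate)
  }))
  overlay <- data.frame(chrom = sim$array$chrom, start = sim$array$start0,
                        end = sim$array$end0,
                        w = params$background_rate * params$enrichment)
  if (!is.null(params$peaks)) {
    pk <- params$peaks
    overlay <- rbind(overlay,
                     data.frame(chrom = pk$chrom, start = pk$start, end = pk$end,
                                w = params$background_rate * pk$fold))
  }
  # subtract overlays from background segments (overlays assumed disjoint)
  seg_list <- list()
  for (i in seq_len(nrow(segs))) {
    ch <- segs$chrom[i]
    ov <- overlay[overlay$chrom == ch, , drop = FALSE]
    ov <- ov[order(ov$start), , drop = FALSE]
    pos <- segs$start[i]
    for (j in seq_len(nrow(ov))) {
      if (ov$start[j] > pos) {
        seg_list[[length(seg_list) + 1]] <-
          data.frame(chrom = ch, start = pos, end = ov$start[j], w = segs$w[i])
      }
      seg_list[[length(seg_list) + 1]] <- ov[j, ]
      pos <- ov$end[j]
    }
    if (pos < segs$end[i]) {
      seg_list[[length(seg_list) + 1]] <-
        data.frame(chrom = ch, start = pos, end = segs$end[i], w = segs$w[i])
    }
  }
  segs <- do.call(rbind, seg_list)
  segs <- segs[segs$end > segs$start & segs$w > 0, , drop = FALSE]
  wt <- (segs$end - segs$start) * segs$w
  with_seed(derive_seed(seed, "fragments"), {
    idx <- sample.int(nrow(segs), n, replace = TRUE, prob = wt)
    start <- floor(segs$start[idx] +
                     stats::runif(n) * (segs$end[idx] - segs$start[idx]))
    len <- round(stats::rnorm(n, params$frag_mean, params$frag_sd))
    len <- pmin(pmax(len, params$frag_min), params$frag_max)
    end <- pmin(start + len, lens[segs$chrom[idx]])
    out <- data.frame(chrom = segs$chrom[idx], start = start, end = end)
    out <- out[out$end > out$start, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
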