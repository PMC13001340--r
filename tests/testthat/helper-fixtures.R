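# Shared fixtures: small genomes and parameter sets used across test files.

# A small three-chromosome genome with a 20-copy 500-bp array on chrB.
toy_spec <- function(copies = 20, unit = 500) {
  sim_genome_spec(
    chrom_lengths = c(chrA = 6e4, chrB = 4e4 + copies * unit, chrC = 6e4),
    array_chrom = "chrB", array_start = 20001,
    unit_length = unit, copy_number = copies)
}

# A genome whose collapsed chromosome lengths are all multiples of the scan
# bin, so every scan bin is full-width (clean null calibration).
aligned_spec <- function(unit = 5080, copies = 100,
                         n_bg_bins = c(60, 40, 60)) {
  sim_genome_spec(
    chrom_lengths = c(chrA = n_bg_bins[1] * unit,
                      chrB = n_bg_bins[2] * unit + copies * unit,
                      chrC = n_bg_bins[3] * unit),
    array_chrom = "chrB", array_start = (n_bg_bins[2] / 2) * unit + 1,
    unit_length = unit, copy_number = copies)
}

# Small image parameters: same physical field and cell density as the
# defaults, rendered at coarser resolution for fast tests.
small_image_params <- function(mode = "wildtype", n_cells = 225, ...) {
  image_sim_params(pixel_um = 0.8, n_slices = 6, n_cells = n_cells,
                   mode = mode, ...)
}

# Brute-force fragment projection: tests membership in each tandem copy
# explicitly instead of using modulo arithmetic.
project_bruteforce <- function(frags, array, consensus_name = "chrHis") {
  a0 <- array$start0; a1 <- array$end0; L <- array$unit_length
  C <- array$copy_number
  out <- list()
  for (i in seq_len(nrow(frags))) {
    ch <- frags$chrom[i]; s <- frags$start[i]; e <- frags$end[i]
    if (ch != array$chrom) {
      out[[length(out) + 1]] <- data.frame(chrom = ch, start = s, end = e,
                                           wrapped = FALSE)
    } else if (e <= a0) {
      out[[length(out) + 1]] <- data.frame(chrom = ch, start = s, end = e,
                                           wrapped = FALSE)
    } else if (s >= a1) {
      out[[length(out) + 1]] <- data.frame(chrom = ch, start = s - (a1 - a0),
                                           end = e - (a1 - a0), wrapped = FALSE)
    } else if (s >= a0 && e <= a1) {
      placed <- FALSE
      for (cp in seq_len(C) - 1) {
        cs <- a0 + cp * L; ce <- cs + L
        if (s >= cs && e <= ce) {
          out[[length(out) + 1]] <- data.frame(
            chrom = consensus_name, start = s - cs, end = e - cs,
            wrapped = FALSE)
          placed <- TRUE
          break
        }
        if (s >= cs && s < ce && e > ce) { # spans the junction at ce
          out[[length(out) + 1]] <- data.frame(
            chrom = consensus_name, start = s - cs, end = L, wrapped = TRUE)
          out[[length(out) + 1]] <- data.frame(
            chrom = consensus_name, start = 0, end = e - ce, wrapped = TRUE)
          placed <- TRUE
          break
        }
      }
      stopifnot(placed)
    } # else: straddles the array edge -> dropped
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Naive per-base pileup for coverage checks.
pileup_bruteforce <- function(frags, chrom_lengths) {
  w <- if ("weight" %in% names(frags)) frags$weight else rep(1, nrow(frags))
  depth <- lapply(chrom_lengths, function(n) numeric(n))
  for (i in seq_len(nrow(frags))) {
    ch <- frags$chrom[i]
    idx <- (frags$start[i] + 1):frags$end[i]
    depth[[ch]][idx] <- depth[[ch]][idx] + w[i]
  }
  depth
}

# Uniform coverage track of a given value (for scan tests).
uniform_track <- function(chrom_lengths, value = 1, bin_size = 2,
                          state = "HGC") {
  values <- lapply(chrom_lengths, function(n) {
    rep(value, ceiling(n / bin_size))
  })
  structure(list(values = values, bin_size = bin_size, state = state,
                 chrom_lengths = chrom_lengths, total_fragments = NA_real_),
            class = "coverage_track")
}
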