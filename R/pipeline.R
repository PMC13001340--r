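#' Run the simulate -> collapse -> coverage -> HGC -> scan pipeline
#'
#' Convenience wrapper chaining the package's occupancy stages on a
#' simulated genome: expand the tandem array, simulate enriched fragments,
#' project them onto the collapsed assembly, pile up binned coverage,
#' CPM-normalize, apply per-gene-copy scaling to the consensus chromosome,
#' and scan the genome in repeat-unit-sized bins.
#'
#' @param spec a [sim_genome_spec()].
#' @param params a [fragment_sim_params()].
#' @param seed integer seed driving both generators.
#' @param bin_size coverage track bin size (bp).
#' @param scan_bin_len scan bin length (bp); defaults to the repeat-unit
#'   length so the consensus chromosome is one bin.
#' @param blacklist optional blacklist data.frame applied before scanning.
#' @return list: `sim`, `fragments`, `assembly`, `projected`, `track`
#'   (HGC state), `scan`.
#' @export
run_array_pipeline <- function(spec, params, seed = 1L, bin_size = 2,
                               scan_bin_len = spec$unit_length,
                               blacklist = NULL) {
  sim <- simulate_genome(spec, seed = seed, sequences = FALSE)
  frags <- simulate_fragments(sim, params, seed = seed)
  asm <- build_collapsed_reference(
    sim$chrom_lengths, spec$array_chrom,
    sim$array$start0 + 1, sim$array$end0,
    unit_length = spec$unit_length, copy_number = spec$copy_number)
  proj <- project_fragments(frags, sim$array, asm$consensus_name)
  track <- compute_coverage(proj, asm, bin_size = bin_size)
  track <- to_cpm(track, total = nrow(frags))
  track <- apply_hgc(track, asm$consensus_name, spec$copy_number)
  if (!is.null(blacklist)) track <- mask_blacklist(track, blacklist)
  scan <- bin_scan(track, bin_len = scan_bin_len)
  list(sim = sim, fragments = frags, assembly = asm, projected = proj,
       track = track, scan = scan)
}
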