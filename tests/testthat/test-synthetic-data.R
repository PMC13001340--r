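test_that("simulate_genome builds exact tandem arrays", {
  spec <- sim_genome_spec(chrom_lengths = c(chr1 = 10000), array_chrom = "chr1",
                          array_start = 2001, unit_length = 500,
                          copy_number = 3)
  sim <- simulate_genome(spec, seed = 1)
  expect_equal(sim$array$end0 - sim$array$start0, 1500)
  expect_equal(sim$array$copy_starts0 - sim$array$start0, c(0, 500, 1000))
  # the rendered sequence really is 3 head-to-tail unit copies
  arr <- substr(as.character(sim$genome[["chr1"]]), 2001, 3500)
  expect_equal(arr, strrep(sim$array$unit_seq, 3))

  # C = 1: expanded genome identical to one with a single unit at the site
  spec1 <- sim_genome_spec(chrom_lengths = c(chr1 = 10000),
                           array_chrom = "chr1", array_start = 2001,
                           array_end = 2500, unit_length = 500,
                           copy_number = 1, unit_seq = strrep("ACGT", 125))
  sim1 <- simulate_genome(spec1, seed = 7)
  expect_equal(nchar(as.character(sim1$genome[["chr1"]])), 10000)
  expect_equal(substr(as.character(sim1$genome[["chr1"]]), 2001, 2500),
               strrep("ACGT", 125))

  # full-scale arithmetic: 100 x 5080 = 508,000 bp array span
  spec_full <- sim_genome_spec()
  sim_full <- simulate_genome(spec_full, sequences = FALSE)
  expect_equal(sim_full$array$end0 - sim_full$array$start0, 508000)

  # strict mode rejects an interval inconsistent with C x L
  spec_bad <- sim_genome_spec(chrom_lengths = c(chr1 = 10000),
                              array_chrom = "chr1", array_start = 2001,
                              array_end = 2600, unit_length = 500,
                              copy_number = 1)
  expect_error(simulate_genome(spec_bad, strict = TRUE), "copy_number")
})

test_that("fragment sampling matches its per-bp weight model", {
  spec <- toy_spec()
  sim <- simulate_genome(spec, seed = 1, sequences = FALSE)
  a_len <- sim$array$end0 - sim$array$start0
  g_len <- sum(sim$chrom_lengths)

  # E = 1: array start density indistinguishable from background
  fr <- simulate_fragments(sim, fragment_sim_params(n_fragments = 2e5,
                                                    enrichment = 1), seed = 3)
  n_in <- sum(fr$chrom == "chrB" & fr$start >= sim$array$start0 &
                fr$start < sim$array$end0)
  ci <- qbinom(c(0.0005, 0.9995), nrow(fr), a_len / g_len)
  expect_gte(n_in, ci[1])
  expect_lte(n_in, ci[2])

  # E = 50: per-bp start-density ratio recovers 50 within 5%
  fr50 <- simulate_fragments(sim, fragment_sim_params(n_fragments = 1e6,
                                                      enrichment = 50),
                             seed = 3)
  n_in <- sum(fr50$chrom == "chrB" & fr50$start >= sim$array$start0 &
                fr50$start < sim$array$end0)
  dens_in <- n_in / a_len
  dens_out <- (nrow(fr50) - n_in) / (g_len - a_len)
  expect_lt(abs(dens_in / dens_out - 50), 50 * 0.05)

  # determinism: same seed gives identical fragment sets
  expect_identical(fr, simulate_fragments(
    sim, fragment_sim_params(n_fragments = 2e5, enrichment = 1), seed = 3))
  # N = 0 is an empty set, not an error; negative E rejected
  expect_equal(nrow(simulate_fragments(
    sim, fragment_sim_params(n_fragments = 0), seed = 1)), 0)
  expect_error(fragment_sim_params(enrichment = -1))
})

test_that("fragment start counts follow the multinomial across regions", {
  spec <- toy_spec()
  sim <- simulate_genome(spec, seed = 1, sequences = FALSE)
  pk <- data.frame(chrom = "chrC", start = 10000, end = 12000, fold = 5)
  fr <- simulate_fragments(
    sim, fragment_sim_params(n_fragments = 1e6, enrichment = 10, peaks = pk),
    seed = 11)
  a0 <- sim$array$start0; a1 <- sim$array$end0
  region <- ifelse(fr$chrom == "chrB" & fr$start >= a0 & fr$start < a1,
                   "array",
                   ifelse(fr$chrom == "chrC" & fr$start >= 10000 &
                            fr$start < 12000, "peak", "bg"))
  a_len <- a1 - a0
  wts <- c(array = a_len * 10, peak = 2000 * 5,
           bg = sum(sim$chrom_lengths) - a_len - 2000)
  obs <- table(factor(region, names(wts)))
  chi <- chisq.test(obs, p = wts / sum(wts))
  expect_gt(chi$p.value, 0.001)
})

test_that("image fields express in the phases the genotype mode dictates", {
  # empty field: background only, no ground-truth expression
  p0 <- small_image_params(n_cells = 0)
  f0 <- simulate_vnc_stack(p0, seed = 1)
  expect_equal(nrow(f0$cells), 0)
  expect_lt(max(f0$stacks$H3), 60) # background noise only

  # wildtype: S-phase cells only; expressing count within binomial bounds
  pw <- small_image_params("wildtype")
  fw <- simulate_vnc_stack(pw, seed = 2)
  expect_true(all(fw$cells$phase[fw$cells$expressing] == "S"))
  ci <- qbinom(c(0.005, 0.995), pw$n_cells, pw$phase_fracs[["S"]])
  expect_gte(sum(fw$cells$expressing), ci[1])
  expect_lte(sum(fw$cells$expressing), ci[2])

  # mutant: expressing set is exactly the S+G2+M cells
  pm <- small_image_params("mutant")
  fm <- simulate_vnc_stack(pm, seed = 2)
  expect_equal(fm$cells$expressing,
               fm$cells$phase %in% c("S", "G2", "M"))

  # ground truth agrees with rendered pixels: expressing annuli are bright
  img <- sum_projection(fw$stacks$H3, z_step_um = pw$z_step_um)
  r_px <- pw$cell_radius_um / pw$pixel_um
  cell_mean <- vapply(seq_len(nrow(fw$cells)), function(i) {
    cx <- fw$cells$x_px[i]; cy <- fw$cells$y_px[i]
    xs <- round(cx + 0.8 * r_px * cos(seq(0, 2 * pi, length.out = 8)))
    ys <- round(cy + 0.8 * r_px * sin(seq(0, 2 * pi, length.out = 8)))
    keep <- xs >= 1 & xs <= nrow(img) & ys >= 1 & ys <= ncol(img)
    mean(img[cbind(xs[keep], ys[keep])])
  }, numeric(1))
  bg_level <- 6 * pw$bg_mean
  expect_true(all(cell_mean[fw$cells$expressing] > bg_level + 100))
  expect_true(all(cell_mean[!fw$cells$expressing] < bg_level + 100))

  # overfull fields are rejected; same seed is bit-identical
  expect_error(simulate_vnc_stack(small_image_params(n_cells = 10000)),
               "packable")
  expect_identical(fw$stacks$H1,
                   simulate_vnc_stack(pw, seed = 2)$stacks$H1)
})

test_that("Ct tables invert the delta-delta-Ct formula at zero noise", {
  prm <- ct_sim_params(noise_sd = 0)
  ct <- simulate_ct_table(prm, seed = 5)
  res <- ddct(ct, "aTub84D", "control")
  mut <- res$summary[res$summary$genotype == "mutant", ]
  expect_equal(setNames(mut$log2fc, mut$gene),
               c(H1 = 0, H2a = 0, H2b = 0, H3 = 1.7, H4 = 1.7))
  ctrl <- res$summary[res$summary$genotype == "control", ]
  expect_equal(ctrl$log2fc, rep(0, nrow(ctrl)))

  # all-zero truth stays zero
  prm0 <- ct_sim_params(noise_sd = 0, log2fc = list(mutant = c(H3 = 0)))
  res0 <- ddct(simulate_ct_table(prm0, seed = 5), "aTub84D", "control")
  expect_equal(res0$summary$log2fc, rep(0, nrow(res0$summary)))

  expect_error(ct_sim_params(genes = c("H3", "ref"), reference_gene = "ref"))
})

test_that("derived sub-seeds separate stages but stay reproducible", {
  expect_identical(derive_seed(1L, "fragments"), derive_seed(1L, "fragments"))
  expect_false(derive_seed(1L, "fragments") == derive_seed(1L, "genome"))
  expect_false(derive_seed(1L, "fragments") == derive_seed(2L, "fragments"))
  s <- vapply(1:1000, derive_seed, integer(1), label = "x")
  expect_true(all(s > 0 & s < 2^31))
})
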