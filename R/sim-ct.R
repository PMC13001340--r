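#' Parameters for simulated qPCR Ct tables
#'
#' Emulates a relative-quantification qPCR design: a panel of target genes
#' plus one reference gene, several genotypes with known true log2 fold
#' changes versus a control genotype, three biological replicates each
#' measured in three technical replicates.
#'
#' @param genes character vector of target genes.
#' @param reference_gene reference (normalizer) gene name.
#' @param genotypes character vector; the first is the control.
#' @param log2fc named list: per genotype, a named numeric of true log2
#'   fold changes per gene (control and reference forced to 0).
#' @param n_bio,n_tech biological / technical replicate counts.
#' @param noise_sd technical Ct noise sd (cycles).
#' @param baseline_ct named numeric of baseline Ct per gene in the control
#'   genotype (defaults: 20 for targets, 15 for the reference).
#' @return object of class `ct_sim_params`.
#' @export
ct_sim_params <- function(genes = c("H1", "H2a", "H2b", "H3", "H4"),
                          reference_gene = "aTub84D",
                          genotypes = c("control", "mutant"),
                          log2fc = list(mutant = c(H1 = 0, H2a = 0, H2b = 0,
                                                   H3 = 1.7, H4 = 1.7)),
                          n_bio = 3, n_tech = 3, noise_sd = 0.2,
                          baseline_ct = NULL) {
  stopifnot(n_bio >= 1, n_tech >= 1, noise_sd >= 0,
            !reference_gene %in% genes, length(genotypes) >= 1)
  if (is.null(baseline_ct)) {
    baseline_ct <- c(stats::setNames(rep(20, length(genes)), genes),
                     stats::setNames(15, reference_gene))
  }
  structure(
    list(genes = genes, reference_gene = reference_gene,
         genotypes = genotypes, log2fc = log2fc, n_bio = n_bio,
         n_tech = n_tech, noise_sd = noise_sd, baseline_ct = baseline_ct),
    class = "ct_sim_params"
  )
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Ct values follow `baseline - log2(relative expression) + bio-rep offset
#' + technical noise`; the bio-rep offset (template loading) applies to all
#' genes of that replicate including the reference, so it cancels in the
#' delta-Ct. The reference gene and the control genotype have true log2
#' fold change 0 by construction, so downstream delta-delta-Ct analysis
#' should recover the `log2fc` values exactly at zero noise.
#'
#' @param params a [ct_sim_params()].
#' @param seed integer seed.
#' @param bio_offset_sd sd of the per-bio-rep loading offset (cycles).
#' @return data.frame: gene, genotype, bio_rep, tech_rep, ct.
#' @export
simulate_ct_table <- function(params, seed = 1L, bio_offset_sd = 0.5) {
  stopifnot(inherits(params, "ct_sim_params"))
  all_genes <- c(params$genes, params$reference_gene)
  with_seed(derive_seed(seed, "ct"), {
    rows <- list()
    for (geno in params$genotypes) {
      lfc <- stats::setNames(rep(0, length(all_genes)), all_genes)
      if (geno %in% names(params$log2fc)) {
        v <- params$log2fc[[geno]]
        lfc[names(v)] <- v
      }
      lfc[params$reference_gene] <- 0
      for (b in seq_len(params$n_bio)) {
        off <- stats::rnorm(1, 0, bio_offset_sd)
        for (g in all_genes) {
          ct0 <- params$baseline_ct[[g]] - lfc[[g]] + off
          rows[[length(rows) + 1]] <- data.frame(
            gene = g, genotype = geno, bio_rep = b,
            tech_rep = seq_len(params$n_tech),
            ct = ct0 + stats::rnorm(params$n_tech, 0, params$noise_sd))
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
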