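#' Simulate per-cell label tables
#'
#' Generates the boolean per-cell label table consumed by
#' [class_counts()]/[group_test()], emulating manually annotated nerve-cord
#' cells. Labels are tied to the simulated cell-cycle phase: `EdU` marks
#' S-phase cells, `pH3S10` mitotic cells, `CycB` G2/M cells. Cytoplasmic
#' FISH follows the genotype mode (S only in wildtype; S, G2 and M in
#' mutant), so EdU-positive cells always carry FISH signal — the observed
#' co-occurrence constraint. Neural markers `Dpn` (stem cells) and `Pros`
#' (differentiating daughters) are drawn with a genotype-specific
#' co-occurrence probability.
#'
#' @param n_embryos embryos per genotype.
#' @param n_cells cells per embryo.
#' @param genotypes character vector of genotype names.
#' @param mode named character: `"wildtype"` or `"mutant"` per genotype.
#' @param phase_fracs cell-cycle phase fractions (G1, S, G2, M; sum 1).
#' @param dpn_frac fraction of cells that are Dpn-positive.
#' @param pros_frac fraction of cells that are Pros-positive.
#' @param dpn_pros_cooccur named numeric per genotype: probability that a
#'   Dpn-positive cell is also Pros-positive.
#' @param seed integer seed.
#' @return data.frame: embryo, genotype, phase, EdU, FISH_cyto,
#'   FISH_nascent, pH3S10, CycB, Dpn, Pros.
#' @export
simulate_cell_table <- function(n_embryos = 4, n_cells = 200,
                                genotypes = c("control", "mutant"),
                                mode = c(control = "wildtype",
                                         mutant = "mutant"),
                                phase_fracs = c(G1 = 0, S = 0.3, G2 = 0.5,
                                                M = 0.2),
                                dpn_frac = 0.15, pros_frac = 0.3,
                                dpn_pros_cooccur = c(control = 0.27,
                                                     mutant = 0.5),
                                seed = 1L) {
  stopifnot(abs(sum(phase_fracs) - 1) < 1e-8,
            all(genotypes %in% names(mode)),
            all(genotypes %in% names(dpn_pros_cooccur)))
  with_seed(derive_seed(seed, "cells"), {
    rows <- lapply(genotypes, function(geno) {
      do.call(rbind, lapply(seq_len(n_embryos), function(e) {
        phase <- sample(names(phase_fracs), n_cells, replace = TRUE,
                        prob = phase_fracs)
        expressing <- if (mode[[geno]] == "mutant") {
          phase %in% c("S", "G2", "M")
        } else {
          phase == "S"
        }
        dpn <- stats::runif(n_cells) < dpn_frac
        pros <- ifelse(dpn,
                       stats::runif(n_cells) < dpn_pros_cooccur[[geno]],
                       stats::runif(n_cells) < pros_frac)
        data.frame(embryo = paste0(geno, "_e", e), genotype = geno,
                   phase = phase,
                   EdU = phase == "S",
                   FISH_cyto = expressing,
                   FISH_nascent = expressing,
                   pH3S10 = phase == "M",
                   CycB = phase %in% c("G2", "M"),
                   Dpn = dpn, Pros = pros)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
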