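#' Parameters for simulated nerve-cord image fields
#'
#' Describes a field of cells whose cytoplasmic histone-mRNA signal depends
#' on cell-cycle phase, genotype mode, and a per-probe maximal output.
#' Defaults emulate the quantified tissue: a 100 x 100 um field, a
#' condensed S-G2-M cell cycle (no G1), and four probes. In `"wildtype"`
#' mode only S-phase cells express, at maximal intensity `max_intensity`;
#' in `"mutant"` mode expression extends through S, G2 and M at
#' `max_output_factor x max_intensity` — probes with factor 1 keep full
#' output, probes with factor < 1 have reduced maximal output.
#'
#' Cytoplasmic signal is rendered as an annulus around each nucleus; pixel
#' intensities are quantized to integers so unit-bin histograms are exact.
#'
#' @param field_um field side length (um); the field is square.
#' @param pixel_um pixel size (um).
#' @param z_step_um z-step between slices (um).
#' @param n_slices number of z slices.
#' @param n_cells number of cells placed in the field (jittered grid;
#'   rejected if it exceeds the packable grid).
#' @param cell_radius_um cell radius (um); the nucleus occupies
#'   `nucleus_frac` of it and the annulus the remainder.
#' @param nucleus_frac nucleus radius as a fraction of cell radius.
#' @param phase_fracs named numeric (G1, S, G2, M) summing to 1. Default
#'   `c(G1 = 0, S = 0.3, G2 = 0.5, M = 0.2)`: the condensed S-G2-M cycle.
#' @param mode `"wildtype"` or `"mutant"`.
#' @param expressing_phases named list of character vectors giving the
#'   phases in which cells express, per mode.
#' @param max_intensity named numeric: per-probe maximal summed intensity
#'   M_g over the projection window (intensity units).
#' @param max_output_factor named numeric in (0, 1]: per-probe mutant
#'   max-output factor f_g.
#' @param bg_mean,bg_sd per-slice background noise (mean, sd).
#' @param signal_cv coefficient of variation of per-pixel signal.
#' @param hist_range named list of c(lo, hi) histogram ranges per probe.
#' @return object of class `image_sim_params`.
#' @export
image_sim_params <- function(field_um = 100, pixel_um = 0.4, z_step_um = 0.3,
                             n_slices = 8, n_cells = 250,
                             cell_radius_um = 2.8, nucleus_frac = 0.4,
                             phase_fracs = c(G1 = 0, S = 0.3, G2 = 0.5, M = 0.2),
                             mode = c("wildtype", "mutant"),
                             expressing_phases = list(
                               wildtype = "S",
                               mutant = c("S", "G2", "M")),
                             max_intensity = c(H3 = 400, H2a = 400,
                                               H1 = 850, CDS = 850),
                             max_output_factor = c(H3 = 1, H2a = 1,
                                                   H1 = 0.5, CDS = 0.5),
                             bg_mean = 20, bg_sd = 5, signal_cv = 0.15,
                             hist_range = list(H3 = c(0, 699), H2a = c(0, 699),
                                               H1 = c(0, 1399), CDS = c(0, 1399))) {
  mode <- match.arg(mode)
  stopifnot(abs(sum(phase_fracs) - 1) < 1e-8, all(phase_fracs >= 0),
            all(max_output_factor > 0), all(max_output_factor <= 1),
            setequal(names(phase_fracs), c("G1", "S", "G2", "M")),
            n_slices >= 1, n_cells >= 0)
  structure(
    list(field_um = field_um, pixel_um = pixel_um, z_step_um = z_step_um,
         n_slices = n_slices, n_cells = n_cells,
         cell_radius_um = cell_radius_um, nucleus_frac = nucleus_frac,
         phase_fracs = phase_fracs, mode = mode,
         expressing_phases = expressing_phases,
         max_intensity = max_intensity, max_output_factor = max_output_factor,
         bg_mean = bg_mean, bg_sd = bg_sd, signal_cv = signal_cv,
         hist_range = hist_range),
    class = "image_sim_params"
  )
}

#' Simulate a nerve-cord-like image stack with ground truth
#'
#' Places cells on a jittered grid, assigns each a cell-cycle phase from
#' the phase fractions, and renders one multi-slice image stack per probe.
#' Expressing cells (phase in the mode's expressing set) receive annular
#' cytoplasmic signal whose *summed* intensity over the projection window
#' averages `M_g` (wildtype) or `f_g * M_g` (mutant); integer quantized,
#' background noise everywhere.
#'
#' @param params an [image_sim_params()].
#' @param seed integer seed.
#' @return list: `stacks` (named list of x*y*z integer arrays, one per
#'   probe), `cells` (data.frame: cell, x_px, y_px, phase, expressing) and
#'   `params`.
#' @export
simulate_vnc_stack <- function(params, seed = 1L) {
  stopifnot(inherits(params, "image_sim_params"))
  npx <- round(params$field_um / params$pixel_um)
  r_px <- params$cell_radius_um / params$pixel_um
  grid_n <- floor(npx / ceiling(2 * r_px + 1))
  if (params$n_cells > grid_n^2) {
    stop("cell count ", params$n_cells, " exceeds packable field (max ",
         grid_n^2, ")")
  }
  probes <- names(params$max_intensity)
  with_seed(derive_seed(seed, paste0("vnc-", params$mode)), {
    # jittered grid placement: guaranteed non-overlapping
    spacing <- npx / grid_n
    if (params$n_cells > 0) {
      slots <- sample.int(grid_n^2, params$n_cells)
      gx <- (slots - 1) %% grid_n
      gy <- (slots - 1) %/% grid_n
      jit <- (spacing - 2 * r_px) / 2
      cx <- (gx + 0.5) * spacing + stats::runif(params$n_cells, -jit, jit)
      cy <- (gy + 0.5) * spacing + stats::runif(params$n_cells, -jit, jit)
      phase <- sample(names(params$phase_fracs), params$n_cells,
                      replace = TRUE, prob = params$phase_fracs)
    } else {
      cx <- cy <- numeric(0)
      phase <- character(0)
    }
    expressing <- phase %in% params$expressing_phases[[params$mode]]
    cells <- data.frame(cell = seq_along(cx), x_px = cx, y_px = cy,
                        phase = phase, expressing = expressing)

    # per-pixel annulus membership, computed once per field within each
    # cell's bounding box (linear indices into the npx x npx slice)
    ann_idx <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      if (!cells$expressing[i]) next
      xr <- max(1, floor(cx[i] - r_px)):min(npx, ceiling(cx[i] + r_px))
      yr <- max(1, floor(cy[i] - r_px)):min(npx, ceiling(cy[i] + r_px))
      d2 <- outer((xr - 0.5 - cx[i])^2, (yr - 0.5 - cy[i])^2, `+`)
      hit <- which(d2 <= r_px^2 & d2 >= (params$nucleus_frac * r_px)^2,
                   arr.ind = TRUE)
      ann_idx[[i]] <- xr[hit[, 1]] + (yr[hit[, 2]] - 1) * npx
    }

    k <- max(1L, round(1.8 / params$z_step_um)) # default projection window
    stacks <- lapply(probes, function(p) {
      m <- params$max_intensity[[p]]
      if (params$mode == "mutant") m <- m * params$max_output_factor[[p]]
      per_slice <- m / k
      stack <- array(0L, dim = c(npx, npx, params$n_slices))
      for (z in seq_len(params$n_slices)) {
        sl <- matrix(stats::rnorm(npx * npx, params$bg_mean, params$bg_sd),
                     nrow = npx)
        for (i in seq_len(nrow(cells))) {
          idx <- ann_idx[[i]]
          if (is.null(idx)) next
          sl[idx] <- sl[idx] +
            stats::rnorm(length(idx), per_slice, params$signal_cv * per_slice)
        }
        stack[, , z] <- pmax(0L, as.integer(round(sl)))
      }
      stack
    })
    names(stacks) <- probes
    list(stacks = stacks, cells = cells, params = params)
  })
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' @param stack x*y*z integer array.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  if (max(stack) > 65535) stop("stack exceeds 16-bit range")
  pages <- lapply(seq_len(dim(stack)[3]), function(z) stack[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-page 16-bit TIFF into an integer stack
#'
#' @param path TIFF path written by [write_stack_tiff()].
#' @return x*y*z integer array.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) {
    arr[, , z] <- as.integer(round(pages[[z]] * 65535))
  }
  arr
}
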