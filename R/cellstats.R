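#' Per-embryo cell-class counts and proportions
#'
#' Evaluates a boolean class definition over the label columns of a cell
#' table and returns, per embryo (and genotype), the count of cells in the
#' class, the denominator, and the proportion. The denominator is either
#' all counted cells of the embryo or a second boolean class.
#'
#' @param cells data.frame with columns `embryo`, `genotype`, and boolean
#'   label columns (e.g. `EdU`, `FISH_cyto`, `FISH_nascent`, `pH3S10`,
#'   `CycB`, `Dpn`, `Pros`).
#' @param class a one-sided formula or character expression over the label
#'   columns, e.g. `~ FISH_cyto & !EdU` or `"Dpn & Pros"`.
#' @param denominator optional second class expression defining the
#'   denominator (default: all cells of the embryo).
#' @return data.frame: embryo, genotype, n, denom, proportion.
#' @export
#' @examples
#' cells <- data.frame(embryo = rep(1, 10), genotype = "wt",
#'                     EdU = rep(c(TRUE, FALSE), 5),
#'                     FISH_cyto = c(rep(TRUE, 8), FALSE, FALSE))
#' class_counts(cells, ~ FISH_cyto & !EdU)
class_counts <- function(cells, class, denominator = NULL) {
  stopifnot(all(c("embryo", "genotype") %in% names(cells)))
  eval_class <- function(expr) {
    e <- if (inherits(expr, "formula")) expr[[2]] else str2lang(expr)
    vars <- all.vars(e)
    unknown <- setdiff(vars, names(cells))
    if (length(unknown)) {
      stop("unknown label(s): ", paste(unknown, collapse = ", "))
    }
    v <- eval(e, cells, baseenv())
    if (!is.logical(v)) stop("class expression must be boolean")
    v
  }
  in_class <- eval_class(class)
  in_denom <- if (is.null(denominator)) rep(TRUE, nrow(cells)) else
    eval_class(denominator)
  key <- interaction(cells$embryo, cells$genotype, drop = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    sel <- key == k
    d <- sum(in_denom & sel)
    if (d == 0) stop("zero denominator for embryo group ", k)
    data.frame(embryo = cells$embryo[sel][1], genotype = cells$genotype[sel][1],
               n = sum(in_class & in_denom & sel), denom = d,
               proportion = sum(in_class & in_denom & sel) / d)
  }))
  rownames(out) <- NULL
  out
}

#' Two-group t-tests over a family of comparisons with BH adjustment
#'
#' Runs a two-tailed t-test per comparison (unpaired equal-variance,
#' unpaired with Welch correction, or paired) and adjusts p-values by
#' Benjamini-Hochberg across the family of comparisons submitted together
#' (the family is caller-defined: whatever is passed in one call).
#' Degenerate paired comparisons with all-zero differences are reported as
#' p = 1 with a warning.
#'
#' @param df data.frame with columns `comparison` (family member id),
#'   `group` (exactly two levels per comparison), `value`, and for paired
#'   designs an id column named `embryo` (pairs are matched on it; if
#'   absent, by order within group).
#' @param design `"unpaired"`, `"unpaired-welch"` or `"paired"`.
#' @return data.frame: comparison, design, n1, n2, estimate (group2 -
#'   group1 mean difference), t, df, p, padj.
#' @export
group_test <- function(df, design = c("unpaired", "unpaired-welch", "paired")) {
  design <- match.arg(design)
  stopifnot(all(c("comparison", "group", "value") %in% names(df)))
  rows <- lapply(unique(df$comparison), function(cmp) {
    d <- df[df$comparison == cmp, , drop = FALSE]
    gl <- unique(d$group)
    if (length(gl) != 2) stop("comparison '", cmp, "' needs exactly 2 groups")
    x <- d[d$group == gl[1], , drop = FALSE]
    y <- d[d$group == gl[2], , drop = FALSE]
    if (nrow(x) < 2 || nrow(y) < 2) {
      stop("comparison '", cmp, "': fewer than 2 values per group")
    }
    if (design == "paired") {
      if (nrow(x) != nrow(y)) stop("paired design requires equal group sizes")
      if ("embryo" %in% names(d)) {
        x <- x[order(x$embryo), , drop = FALSE]
        y <- y[order(y$embryo), , drop = FALSE]
        if (!identical(x$embryo, y$embryo)) {
          stop("paired design: embryo ids do not match across groups")
        }
      }
      diffs <- y$value - x$value
      if (stats::sd(diffs) == 0) {
        warning("comparison '", cmp, "': zero-variance paired differences; p = 1")
        return(data.frame(comparison = cmp, design = design, n1 = nrow(x),
                          n2 = nrow(y), estimate = mean(diffs), t = 0,
                          df = nrow(x) - 1, p = 1))
      }
      tt <- stats::t.test(y$value, x$value, paired = TRUE)
    } else {
      tt <- stats::t.test(y$value, x$value, paired = FALSE,
                          var.equal = (design == "unpaired"))
    }
    data.frame(comparison = cmp, design = design, n1 = nrow(x), n2 = nrow(y),
               estimate = mean(y$value) - mean(x$value),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Delta-delta-Ct relative quantification
#'
#' Standard Livak analysis: technical replicates are averaged per (gene,
#' genotype, biological replicate); delta-Ct = Ct_gene - Ct_reference
#' within each (genotype, bio-rep); delta-delta-Ct = delta-Ct -
#' mean(delta-Ct of the control genotype) per gene; log2 fold change =
#' -delta-delta-Ct and fold change = 2^(-delta-delta-Ct).
#'
#' @param ct data.frame: gene, genotype, bio_rep, tech_rep, ct.
#' @param reference_gene normalizer gene (must be present for every
#'   (genotype, bio_rep)).
#' @param control_genotype the genotype used as the comparison baseline.
#' @return list with `per_rep` (gene, genotype, bio_rep, ddct, log2fc) and
#'   `summary` (gene, genotype, log2fc, sd, sem, fold_change, n).
#' @export
ddct <- function(ct, reference_gene, control_genotype) {
  stopifnot(all(c("gene", "genotype", "bio_rep", "ct") %in% names(ct)),
            any(ct$gene == reference_gene),
            any(ct$genotype == control_genotype))
  if (any(ct$ct <= 0)) stop("non-positive Ct value")
  # average technical replicates
  avg <- stats::aggregate(ct ~ gene + genotype + bio_rep, data = ct, FUN = mean)
  ref <- avg[avg$gene == reference_gene, c("genotype", "bio_rep", "ct")]
  names(ref)[3] <- "ref_ct"
  tgt <- avg[avg$gene != reference_gene, , drop = FALSE]
  m <- merge(tgt, ref, by = c("genotype", "bio_rep"))
  if (nrow(m) < nrow(tgt)) {
    stop("reference gene missing for some (genotype, bio_rep)")
  }
  m$dct <- m$ct - m$ref_ct
  ctrl <- m[m$genotype == control_genotype, , drop = FALSE]
  ctrl_mean <- stats::aggregate(dct ~ gene, data = ctrl, FUN = mean)
  names(ctrl_mean)[2] <- "ctrl_dct"
  m <- merge(m, ctrl_mean, by = "gene")
  m$ddct <- m$dct - m$ctrl_dct
  m$log2fc <- -m$ddct
  per_rep <- m[order(m$gene, m$genotype, m$bio_rep),
               c("gene", "genotype", "bio_rep", "ddct", "log2fc")]
  rownames(per_rep) <- NULL
  agg <- stats::aggregate(log2fc ~ gene + genotype, data = per_rep,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  summary <- data.frame(gene = agg$gene, genotype = agg$genotype,
                        log2fc = agg$log2fc[, "mean"],
                        sd = agg$log2fc[, "sd"],
                        sem = agg$log2fc[, "sd"] / sqrt(agg$log2fc[, "n"]),
                        fold_change = 2^agg$log2fc[, "mean"],
                        n = agg$log2fc[, "n"])
  summary <- summary[order(summary$gene, summary$genotype), , drop = FALSE]
  rownames(summary) <- NULL
  list(per_rep = per_rep, summary = summary)
}
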