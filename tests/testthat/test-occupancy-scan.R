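test_that("bin scan tiles, sums and ranks as specified", {
  # uniform value 1 over three 15,240-bp chromosomes: nine bins, all 5080
  lens <- c(c1 = 15240, c2 = 15240, c3 = 15240)
  sc <- bin_scan(uniform_track(lens, value = 1), bin_len = 5080)
  expect_equal(nrow(sc), 9)
  expect_equal(sc$signal, rep(5080, 9))
  expect_equal(sc$rank, rep(1L, 9)) # ties share the minimum rank

  # a 10x consensus bin ranks first
  tr <- uniform_track(c(c1 = 15240, chrHis = 5080), value = 1)
  tr$values$chrHis[] <- 10
  sc2 <- bin_scan(tr, bin_len = 5080)
  expect_equal(sc2$rank[sc2$chrom == "chrHis"], 1L)

  # trailing partial bin retained and flagged
  sc3 <- bin_scan(uniform_track(c(c1 = 12000), value = 1), bin_len = 5080)
  expect_equal(sc3$end, c(5080, 10160, 12000))
  expect_equal(sc3$partial, c(FALSE, FALSE, TRUE))
  expect_equal(sc3$signal[3], 12000 - 10160)

  expect_error(bin_scan(uniform_track(c(c1 = 100), bin_size = 10),
                        bin_len = 5), "smaller")
  expect_error(bin_scan(uniform_track(c(c1 = 100), state = "CPM"))) # state
})

test_that("bin sums are invariant to the track bin size", {
  lens <- c(chrA = 20000, chrHis = 5080)
  set.seed(3)
  fr <- data.frame(chrom = sample(names(lens), 2000, replace = TRUE))
  fr$start <- floor(runif(2000) * (lens[fr$chrom] - 80))
  fr$end <- fr$start + 80 # edges at multiples of 10: aligned to both grids
  fr$start <- round(fr$start / 10) * 10
  fr$end <- fr$start + 80
  for (bs in c(2, 10)) {
    tr <- apply_hgc(to_cpm(compute_coverage(fr, lens, bin_size = bs),
                           total = nrow(fr)), "chrHis", 10)
    assign(paste0("s", bs), bin_scan(tr, bin_len = 5080)$signal)
  }
  expect_equal(s2, s10)
})

test_that("Manhattan layout is deterministic with the consensus last", {
  lens <- c(c1 = 10160, chrHis = 5080, c2 = 5080)
  tr <- uniform_track(lens, value = 1)
  tr$values$chrHis[] <- 50
  sc <- bin_scan(tr, bin_len = 5080)
  mh <- manhattan_table(sc, top_k = 1)
  expect_equal(mh$chrom, c("c1", "c1", "c2", "chrHis"))
  expect_equal(mh$cum_pos, c(0, 5080, 10160, 15240))
  expect_equal(mh$label[mh$chrom == "chrHis"], "chrHis:0-5080")
  # single chromosome: cumulative coordinate equals bin start
  sc1 <- bin_scan(uniform_track(c(c1 = 15240), value = 1), bin_len = 5080)
  expect_equal(manhattan_table(sc1)$cum_pos, sc1$start)
  # top-k labels are the k largest sums
  mh5 <- manhattan_table(sc, top_k = 2)
  lab <- mh5[!is.na(mh5$label), ]
  expect_setequal(lab$rank, c(1L, 2L))
  expect_error(manhattan_table(sc[0, ]), "empty")
})

test_that("gene matrices rescale bodies and respect strand", {
  lens <- c(chr1 = 20000)
  # constant track: every row constant regardless of length or strand
  trc <- uniform_track(lens, value = 3, bin_size = 2)
  genes <- data.frame(chrom = "chr1",
                      start = c(1000, 5000, 9000),
                      end = c(3000, 8113, 9600),
                      strand = c("+", "-", "+"),
                      name = c("g2000", "godd", "gshort"))
  m <- gene_matrix(trc, genes)
  expect_equal(dim(m), c(3, 300))
  expect_true(all(abs(m - 3) < 1e-9))

  # identity resampling for a body of exactly 2000 bp on a varying track
  set.seed(9)
  trv <- uniform_track(lens, value = 0, bin_size = 10)
  trv$values$chr1 <- rnorm(2000)^2
  m1 <- gene_matrix(trv, genes[1, ], col_width = 10)
  direct <- trv$values$chr1[(1000 / 10 + 1):(3000 / 10)]
  expect_equal(unname(m1[1, 51:250]), direct)

  # linear ramp: scaled row equals the analytic resampled ramp
  trr <- uniform_track(lens, value = 0, bin_size = 2)
  trr$values$chr1 <- seq_along(trr$values$chr1) # value = bin index
  g <- data.frame(chrom = "chr1", start = 4000, end = 10000, strand = "+",
                  name = "ramp")
  mr <- gene_matrix(trr, g, col_width = 10)
  glen <- 6000
  analytic <- vapply(1:200, function(j) {
    a <- 4000 + glen * (j - 1) / 200
    b <- 4000 + glen * j / 200
    # mean of value(x) = floor(x/2)+1 over [a,b): midpoint of the ramp
    (a + b) / 2 / 2 + 0.5
  }, numeric(1))
  expect_true(max(abs(unname(mr[1, 51:250]) - analytic)) < 1)

  # minus strand flips the row
  gm <- g; gm$strand <- "-"
  mm <- gene_matrix(trr, gm, col_width = 10)
  expect_equal(unname(mm[1, ]), rev(unname(mr[1, ])))

  # rows come back sorted by total signal, descending
  m3 <- gene_matrix(trr, genes)
  expect_equal(order(attr(m3, "totals"), decreasing = TRUE), 1:3)
  expect_error(gene_matrix(trc, data.frame(chrom = "chr1", start = 19000,
                                           end = 21000, strand = "+",
                                           name = "off")), "bounds")
})

test_that("Ward clustering isolates the high-signal rows", {
  # two point masses: 5 rows at 100, 395 at 0 -> the 5 form one cluster
  m <- rbind(matrix(100, 5, 20), matrix(0, 395, 20))
  rownames(m) <- c(paste0("hist", 1:5), paste0("bg", 1:395))
  cl <- cluster_rows(m, k = 2)
  expect_equal(length(unique(cl[1:5])), 1)
  expect_false(cl[1] %in% cl[6:400])

  # k = n: every row its own cluster
  cln <- cluster_rows(m[1:10, ], k = 10)
  expect_equal(sort(unname(cln)), 1:10)

  # permutation invariance of the partition
  set.seed(4)
  mm <- matrix(rnorm(200), 20, 10)
  rownames(mm) <- paste0("r", 1:20)
  perm <- sample(20)
  cl1 <- cluster_rows(mm, k = 3)
  cl2 <- cluster_rows(mm[perm, ], k = 3)[rownames(mm)]
  co <- function(cl) outer(cl, cl, "==")
  expect_identical(co(cl1), co(cl2))

  expect_error(cluster_rows(mm, k = 0))
  expect_error(cluster_rows(mm, k = 21))
})

test_that("signal/DE merge joins, reports and sorts", {
  sig <- data.frame(gene = c("H3", "H4", "geneA", "geneB"),
                    signal = c(500, 450, 5, 3))
  de <- data.frame(gene = c("H3", "H4", "geneA", "geneC"),
                   log2fc = c(1.7, 1.6, -2, 3), padj = c(1e-60, 1e-55, 1e-4, 1e-3))
  expect_message(out <- merge_signal_with_de(sig, de), "1 gene")
  expect_equal(out$gene, c("H3", "H4", "geneA")) # sorted by signal
  expect_equal(out$log2fc, c(1.7, 1.6, -2))
  expect_error(merge_signal_with_de(sig, data.frame(gene = "x", log2fc = 0)),
               "no overlapping")
  de0 <- de; de0$log2fc <- 0
  expect_equal(suppressMessages(merge_signal_with_de(sig, de0))$log2fc,
               rep(0, 3))
})

test_that("array genes separate from DEGs on the signal axis", {
  # construction mirroring the occupancy-vs-expression comparison: only the
  # five array genes carry high signal; no DEG comes close on that axis
  set.seed(11)
  sig <- data.frame(
    gene = c(paste0("His", 1:5), paste0("deg", 1:50)),
    signal = c(rnorm(5, 500, 20), abs(rnorm(50, 2, 1))))
  de <- data.frame(gene = sig$gene,
                   log2fc = c(rep(0, 5), rnorm(50, 0, 2)),
                   padj = runif(55))
  out <- merge_signal_with_de(sig, de)
  expect_setequal(out$gene[1:5], paste0("His", 1:5))
  expect_gt(min(out$signal[1:5]), 10 * max(out$signal[-(1:5)]))
})
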