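test_that("window tiling covers the region exactly", {
  t60 <- tile_windows(3000, 50)
  expect_equal(nrow(t60), 60L)
  expect_equal(t60$start[1], 0L)
  expect_equal(t60$end[60], 3000L)
  expect_equal(tile_windows(100, 50)$start, c(0L, 50L))
  expect_error(tile_windows(3000, 49), "does not divide")
  # random valid tilings: disjoint cover of [0, L)
  set.seed(4)
  for (i in 1:25) {
    w <- sample(c(10, 20, 25, 50, 100), 1)
    L <- w * sample(5:80, 1)
    tl <- tile_windows(L, w)
    expect_equal(tl$start, c(0L, tl$end[-nrow(tl)]))  # abut, no overlap
    expect_equal(tl$end[nrow(tl)], L)
  }
})

test_that("window aggregation conserves gene totals and computes means", {
  ann <- make_annotated(meth = 5, unmeth = 15, position = 151L)
  ws <- aggregate_window_counts(ann, region_length = 300, window_size = 50)
  w3 <- ws[ws$window_index == 3 & ws$context == "CpG", ]
  expect_equal(w3$meth_reads, 5L)
  expect_equal(w3$mean_pct, 25.0)
  empty <- ws[ws$window_index == 0 & ws$context == "CpG", ]
  expect_equal(empty$meth_reads, 0L)
  expect_true(is.na(empty$mean_pct))

  set.seed(17)
  big <- data.frame(
    gene_id = "g", position = sample(0:2999, 800), strand = "+",
    meth_reads = rpois(800, 3), unmeth_reads = rpois(800, 8),
    context = sample(c("CpG", "CHG", "CHH"), 800, replace = TRUE),
    region_label = "promoter", stringsAsFactors = FALSE
  )
  ws2 <- aggregate_window_counts(big, 3000, 50)
  expect_equal(sum(ws2$meth_reads[ws2$context == "all"]),
               sum(big$meth_reads))
  for (cx in c("CpG", "CHG", "CHH"))
    expect_equal(sum(ws2$unmeth_reads[ws2$context == cx]),
                 sum(big$unmeth_reads[big$context == cx]))
})

test_that("Fisher test: degenerate and closed-form cases", {
  expect_equal(fisher_exact_two_tailed(5, 5, 5, 5), 1.0)
  # zero margin carries no information
  expect_equal(fisher_exact_two_tailed(0, 0, 3, 7), 1.0)
  expect_equal(fisher_exact_two_tailed(0, 5, 0, 7), 1.0)
  # [[0,50],[50,0]]: only the two extreme tables qualify -> 2/choose(100,50)
  expect_equal(fisher_exact_two_tailed(0, 50, 50, 0), 2 / choose(100, 50),
               tolerance = 1e-9)
  expect_lt(fisher_exact_two_tailed(0, 50, 50, 0), 1e-20)
  expect_error(fisher_exact_two_tailed(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher test agrees with the enumeration oracle and fisher.test", {
  p <- fisher_exact_two_tailed(10, 90, 40, 60)
  expect_equal(p, oracle_fisher(10, 90, 40, 60), tolerance = 1e-9)
  expect_equal(p, stats::fisher.test(matrix(c(10, 90, 40, 60), 2,
                                            byrow = TRUE))$p.value,
               tolerance = 1e-7)
  set.seed(23)
  for (i in 1:200) {
    t <- rpois(4, sample(c(3, 20, 100), 1))
    expect_equal(fisher_exact_two_tailed(t[1], t[2], t[3], t[4]),
                 oracle_fisher(t[1], t[2], t[3], t[4]), tolerance = 1e-9)
  }
})

test_that("DMR calling applies the strict >20-point rule and flags no-calls", {
  mkwin <- function(meth, unmeth) data.frame(
    gene_id = "g", window_index = 0L, context = "CpG",
    meth_reads = meth, unmeth_reads = unmeth,
    mean_pct = 100 * meth / (meth + unmeth), stringsAsFactors = FALSE)
  # identical groups: p = 1, delta = 0
  same <- call_dmrs(mkwin(10, 90), mkwin(10, 90))
  expect_equal(same$p_value, 1.0)
  expect_equal(same$delta_pct, 0)
  expect_false(same$is_dmr)
  # clear effect: 5% vs 40%
  hit <- call_dmrs(mkwin(5, 95), mkwin(40, 60))
  expect_equal(hit$delta_pct, 35)
  expect_lt(hit$p_value, 0.05)
  expect_true(hit$is_dmr)
  expect_equal(hit$p_value, oracle_fisher(5, 95, 40, 60), tolerance = 1e-9)
  # delta exactly 20.0 points is NOT a DMR even at tiny p
  edge <- call_dmrs(mkwin(0, 500), mkwin(100, 400))
  expect_equal(edge$delta_pct, 20)
  expect_lt(edge$p_value, 0.05)
  expect_false(edge$is_dmr)
  # zero coverage on one side -> no call
  nc <- call_dmrs(mkwin(0, 0), mkwin(10, 10))
  expect_true(nc$no_call)
  expect_true(is.na(nc$is_dmr))
  # mismatched grids are a hard error
  other <- mkwin(1, 1); other$window_index <- 1L
  expect_error(call_dmrs(mkwin(1, 1), other), "do not match")
})

test_that("swapping group labels flips delta and preserves p", {
  set.seed(29)
  ann_a <- make_annotated(meth = rpois(40, 3), unmeth = rpois(40, 10),
                          position = sample(0:299, 40))
  ann_b <- make_annotated(meth = rpois(40, 6), unmeth = rpois(40, 7),
                          position = ann_a$position)
  wa <- aggregate_window_counts(ann_a, 300, 50)
  wb <- aggregate_window_counts(ann_b, 300, 50)
  ab <- call_dmrs(wa, wb)
  ba <- call_dmrs(wb, wa)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$delta_pct, -ba$delta_pct)
  expect_equal(ab$is_dmr, ba$is_dmr)
})

test_that("DMG roll-up requires one DMR window in at least one context", {
  calls <- data.frame(
    gene_id = rep(c("g1", "g2"), each = 4),
    window_index = 0L,
    context = rep(c("CpG", "CHG", "CHH", "all"), 2),
    is_dmr = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  dmg <- summarize_dmgs(calls)
  expect_true(dmg$is_dmg_CpG[dmg$gene_id == "g1"])
  expect_true(dmg$is_dmg_any[dmg$gene_id == "g1"])
  expect_false(dmg$is_dmg_any[dmg$gene_id == "g2"])
  expect_equal(attr(dmg, "dmg_any_fraction"), 0.5)
})

test_that("metaprofile averages genes within replicates, then replicates", {
  ws1 <- data.frame(gene_id = c("g1", "g2"), window_index = 0L,
                    context = "all", meth_reads = 1L, unmeth_reads = 1L,
                    mean_pct = c(10, 30), stringsAsFactors = FALSE)
  mp <- metaprofile(list(r1 = ws1), "all")
  expect_equal(mp$mean_pct, 20)
  # second replicate where g2 has no coverage: its NA is excluded, not zero
  ws2 <- ws1; ws2$mean_pct <- c(40, NA)
  mp2 <- metaprofile(list(r1 = ws1, r2 = ws2), "all")
  expect_equal(mp2$mean_pct, mean(c(20, 40)))
  expect_equal(mp2$n_replicates, 2)
})

test_that("window BED export is 0-based half-open", {
  bed <- windows_as_bed(c("g1"), 300, 50)
  expect_equal(nrow(bed), 6L)
  expect_equal(bed$start[1], 0L)
  expect_equal(bed$end[1], 50L)
  expect_equal(bed$name[6], "g1_w5")
})
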