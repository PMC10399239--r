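test_that("site methylation fraction: arithmetic, missing, saturation", {
  expect_equal(site_methylation_fraction(5L, 15L), 0.25)
  expect_true(is.na(site_methylation_fraction(0L, 0L)))
  expect_equal(site_methylation_fraction(7L, 0L), 1.0)
  expect_equal(site_methylation_fraction(c(5L, 0L, 7L), c(15L, 0L, 0L)),
               c(0.25, NA, 1.0))
  # below min_coverage -> missing
  expect_true(is.na(site_methylation_fraction(1L, 1L, min_coverage = 5L)))
})

test_that("gene mean methylation is read-weighted, not a site mean", {
  a <- make_annotated(meth = c(1, 9), unmeth = c(9, 1))
  expect_equal(gene_mean_methylation(a), 50.0)
  # 1/10 and 90/100: read weighting gives 91/110, not the site mean 50
  b <- make_annotated(meth = c(1, 90), unmeth = c(9, 10))
  expect_equal(gene_mean_methylation(b), 100 * 91 / 110)
  z <- make_annotated(meth = c(0, 0), unmeth = c(10, 10))
  expect_equal(gene_mean_methylation(z), 0.0)
  none <- make_annotated(meth = 0, unmeth = 0)
  expect_true(is.na(gene_mean_methylation(none)))
})

test_that("per-context mean: weighted and literal modes diverge as documented", {
  one <- make_annotated(meth = 8, unmeth = 2)
  expect_equal(context_mean_methylation(one, "CpG", "weighted"), 80.0)
  expect_equal(context_mean_methylation(one, "CpG", "literal"), 80.0)
  two <- make_annotated(meth = c(8, 0), unmeth = c(2, 10))
  expect_equal(context_mean_methylation(two, "CpG", "weighted"), 40.0)
  # literal divides again by the context site count: 8/(20*2)
  expect_equal(context_mean_methylation(two, "CpG", "literal"), 20.0)
  expect_error(context_mean_methylation(two, "CpG", "typo"))
})

test_that("site classification follows the level-zero / level-positive rule", {
  pooled <- make_annotated(meth = c(0, 1, 0), unmeth = c(30, 29, 0))
  got <- classify_sites(pooled)$state
  expect_equal(got, c("unmethylated", "methylated", "uninterrogated"))
})

test_that("context decomposition recovers hand-tallied shares and closes at 100", {
  pooled <- rbind(
    make_annotated(meth = rep(0, 6), unmeth = rep(5, 6), context = "CHH",
                   position = 1:6 * 3L),
    make_annotated(meth = rep(0, 3), unmeth = rep(5, 3), context = "CHG",
                   position = 100L + 1:3 * 3L),
    make_annotated(meth = 0, unmeth = 5, context = "CpG", position = 200L)
  )
  d <- context_fraction_decomposition(classify_sites(pooled),
                                      scope = "promoter")
  expect_equal(d$pct_of_unmethylated[match(c("CHH", "CHG", "CpG"),
                                           d$context)], c(60, 30, 10))
  expect_equal(sum(d$pct_of_unmethylated), 100, tolerance = 1e-9)
  # all sites one context -> 100 / 0 / 0
  solo <- classify_sites(make_annotated(meth = rep(1, 4), unmeth = rep(1, 4),
                                        context = "CHG"))
  d2 <- context_fraction_decomposition(solo, scope = "promoter")
  expect_equal(d2$pct_of_methylated[d2$context == "CHG"], 100)
  expect_equal(sum(d2$pct_of_methylated), 100, tolerance = 1e-9)
  # empty stratum -> NULL
  expect_null(context_fraction_decomposition(solo, scope = "body"))
})

test_that("decomposition shares match a brute-force tally on simulated strata", {
  set.seed(31)
  pooled <- data.frame(
    gene_id = "g", position = seq_len(500) * 3L, strand = "+",
    meth_reads = rbinom(500, 20, 0.1), unmeth_reads = 20L,
    context = sample(c("CpG", "CHG", "CHH"), 500, replace = TRUE),
    region_label = "promoter", stringsAsFactors = FALSE
  )
  cl <- classify_sites(pooled)
  d <- context_fraction_decomposition(cl, scope = "promoter")
  for (cx in c("CpG", "CHG", "CHH")) {
    expect_equal(d$n_methylated[d$context == cx],
                 sum(cl$state == "methylated" & cl$context == cx))
    expect_equal(d$pct_of_methylated[d$context == cx],
                 100 * sum(cl$state == "methylated" & cl$context == cx) /
                   sum(cl$state == "methylated"))
  }
  expect_equal(sum(d$pct_of_unmethylated), 100, tolerance = 1e-9)
  expect_equal(sum(d$pct_of_methylated), 100, tolerance = 1e-9)
})

test_that("shared-context percentages follow set arithmetic in union mode", {
  mk <- function(meth_sites, all_sites = 1:6) {
    classify_sites(make_annotated(
      meth = as.integer(all_sites %in% meth_sites),
      unmeth = rep(10L, length(all_sites)), position = all_sites * 3L))
  }
  # identical methylated sets -> 100% in both modes
  a <- mk(1:3); b <- mk(1:3)
  for (m in c("union", "either_group_mean")) {
    got <- shared_context_percentages(a, b, "CpG", "promoter", m)
    expect_equal(got$pct_shared_methylated, 100)
    expect_equal(got$pct_shared_unmethylated, 100)
  }
  # disjoint methylated sets -> 0% shared methylated
  expect_equal(shared_context_percentages(mk(1:3), mk(4:6), "CpG",
                                          "promoter")$pct_shared_methylated, 0)
  # A {1,2,3}, B {2,3,4}: intersection 2, union 4 -> 50%
  got <- shared_context_percentages(mk(1:3), mk(2:4), "CpG", "promoter")
  expect_equal(got$pct_shared_methylated, 50)
  # either_group_mean: 2 / mean(3,3) -> 66.67%
  got2 <- shared_context_percentages(mk(1:3), mk(2:4), "CpG", "promoter",
                                     "either_group_mean")
  expect_equal(got2$pct_shared_methylated, 100 * 2 / 3)
})

test_that("shared percentages are symmetric in union mode and drop uninterrogated", {
  set.seed(8)
  mk <- function() classify_sites(make_annotated(
    meth = rbinom(50, 5, 0.3), unmeth = rbinom(50, 10, 0.8),
    position = 1:50 * 3L))
  a <- mk(); b <- mk()
  a$meth_reads[1:5] <- 0L; a$unmeth_reads[1:5] <- 0L
  a <- classify_sites(a)
  ab <- shared_context_percentages(a, b, "CpG", "promoter")
  ba <- shared_context_percentages(b, a, "CpG", "promoter")
  expect_equal(ab$pct_shared_methylated, ba$pct_shared_methylated)
  expect_equal(ab$pct_shared_unmethylated, ba$pct_shared_unmethylated)
  expect_equal(ab$n_sites_compared, 45L)
})

test_that("raising min_coverage never increases interrogated sites", {
  set.seed(13)
  pooled <- make_annotated(meth = rpois(200, 2), unmeth = rpois(200, 6),
                           position = 1:200 * 3L)
  prev <- Inf
  for (mc in c(1, 3, 5, 10, 20)) {
    n <- sum(classify_sites(pooled, min_coverage = mc)$state !=
               "uninterrogated")
    expect_lte(n, prev)
    prev <- n
  }
})
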