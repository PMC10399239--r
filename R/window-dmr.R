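#' Tile a region into consecutive windows
#'
#' Half-open windows `[k*w, (k+1)*w)` covering `[0, L)` exactly: a 3 kb
#' region at the default 50 bp yields 60 windows with no gap or overlap.
#'
#' @param length_nt Region length `L`.
#' @param window_size Window width `w`; must divide `L`.
#' @return `data.frame` with `window_index` (0-based), `start`, `end`
#'   (half-open).
#' @export
tile_windows <- function(length_nt, window_size = 50L) {
  length_nt <- as.integer(length_nt)
  window_size <- as.integer(window_size)
  if (window_size <= 0L || length_nt %% window_size != 0L)
    stop(sprintf("window_size %d does not divide region length %d",
                 window_size, length_nt))
  k <- 0:(length_nt %/% window_size - 1L)
  data.frame(window_index = k, start = k * window_size,
             end = (k + 1L) * window_size)
}

#' Aggregate site counts into window statistics
#'
#' Sums methylated and unmethylated reads over interrogated sites (both
#' strands) per gene, window and context, plus an `"all"` row pooling the
#' three contexts. Window sums conserve gene totals. The per-window mean is
#' `100 * meth / (meth + unmeth)`, `NA` where the window has no coverage.
#'
#' @param annotated Annotated counts (one sample or a pooled group).
#' @param region_length Region length shared by all genes.
#' @param window_size Window width (default 50).
#' @param min_coverage Per-site interrogation threshold.
#' @return `data.frame` with `gene_id`, `window_index`, `context`
#'   (CpG/CHG/CHH/all), `meth_reads`, `unmeth_reads`, `mean_pct`; complete
#'   grid, zero-filled.
#' @export
aggregate_window_counts <- function(annotated, region_length = 3000L,
                                    window_size = 50L, min_coverage = 1L) {
  n_win <- nrow(tile_windows(region_length, window_size))
  df <- annotated[annotated$context %in% c("CpG", "CHG", "CHH"), , drop = FALSE]
  cov <- df$meth_reads + df$unmeth_reads
  df <- df[cov >= min_coverage & cov > 0L, , drop = FALSE]
  genes <- sort(unique(annotated$gene_id))
  contexts <- c("CpG", "CHG", "CHH", "all")
  grid <- expand.grid(window_index = 0:(n_win - 1L), context = contexts,
                      gene_id = genes, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("gene_id", "window_index", "context")]
  grid$meth_reads <- 0L
  grid$unmeth_reads <- 0L
  if (nrow(df)) {
    win <- df$position %/% window_size
    add <- function(sub_ctx_key, meth, unmeth) {
      m <- match(sub_ctx_key, paste(grid$gene_id, grid$window_index,
                                    grid$context, sep = "\r"))
      grid$meth_reads[m] <<- grid$meth_reads[m] + as.integer(meth)
      grid$unmeth_reads[m] <<- grid$unmeth_reads[m] + as.integer(unmeth)
    }
    key_ctx <- paste(df$gene_id, win, df$context, sep = "\r")
    s <- rowsum(cbind(df$meth_reads, df$unmeth_reads), key_ctx, reorder = FALSE)
    add(rownames(s), s[, 1L], s[, 2L])
    key_all <- paste(df$gene_id, win, "all", sep = "\r")
    s <- rowsum(cbind(df$meth_reads, df$unmeth_reads), key_all, reorder = FALSE)
    add(rownames(s), s[, 1L], s[, 2L])
  }
  covw <- grid$meth_reads + grid$unmeth_reads
  grid$mean_pct <- ifelse(covw > 0L, 100 * grid$meth_reads / covw, NA_real_)
  grid <- grid[order(grid$gene_id, grid$window_index,
                     match(grid$context, contexts)), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Two-tailed Fisher's exact test for 2x2 count tables
#'
#' Exact two-sided p-value by the standard hypergeometric rule: the sum of
#' the probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table (ties admitted
#' within a relative tolerance of 1e-7). Vectorized over tables
#' `[[a, b], [c, d]]` = `[[meth_A, unmeth_A], [meth_B, unmeth_B]]`. A table
#' with any zero margin carries no information and returns p = 1.
#'
#' @param a,b,c,d Non-negative integer vectors (recycled to common length).
#' @param rel_tol Relative tolerance for point-probability ties.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
fisher_exact_two_tailed <- function(a, b, c, d, rel_tol = 1e-7) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(is.na(c(a, b, c, d))) || any(c(a, b, c, d) < 0) ||
      any(c(a, b, c, d) != floor(c(a, b, c, d))))
    stop("counts must be non-negative integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  p <- rep(1, n)
  todo <- which(r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0)
  for (i in todo) {
    lo <- max(0, c1[i] - r2[i]); hi <- min(r1[i], c1[i])
    x <- lo:hi
    probs <- stats::dhyper(x, r1[i], r2[i], c1[i])
    p0 <- probs[a[i] - lo + 1]
    p[i] <- min(1, sum(probs[probs <= p0 * (1 + rel_tol)]))
  }
  p
}

#' Call differentially methylated 50-bp windows
#'
#' Per window and context: a two-tailed Fisher's exact test on the 2x2 table
#' of pooled methylated/unmethylated read counts of the two groups, and the
#' signed methylation difference in percentage points
#' (`delta_pct = pct_B - pct_A`). A window is a DMR iff `p < alpha` and
#' `|delta_pct| > delta_threshold` — the effect-size inequality is strict,
#' so a difference of exactly 20 points is never called. Windows where either
#' group has zero coverage get no call (`is_dmr = NA`, flagged `no_call`).
#' A Benjamini-Hochberg column is reported per context for reference but
#' never drives the call.
#'
#' @param win_a,win_b Window statistics of groups A and B from
#'   [aggregate_window_counts()]; must be on the identical grid.
#' @param alpha Significance level on the raw p-value (default 0.05).
#' @param delta_threshold Effect threshold in percentage points (default 20).
#' @param comparison Label recorded in the output.
#' @return `data.frame` with counts and percentages for both groups,
#'   `delta_pct`, `p_value`, `p_adj_BH`, `no_call`, `is_dmr`. The thresholds
#'   are attached as attributes `alpha` and `delta_threshold`.
#' @export
call_dmrs <- function(win_a, win_b, alpha = 0.05, delta_threshold = 20,
                      comparison = "B_vs_A") {
  key_a <- paste(win_a$gene_id, win_a$window_index, win_a$context, sep = "\r")
  key_b <- paste(win_b$gene_id, win_b$window_index, win_b$context, sep = "\r")
  if (length(key_a) != length(key_b) || !all(key_a == key_b))
    stop("window grids of the two groups do not match")
  cov_a <- win_a$meth_reads + win_a$unmeth_reads
  cov_b <- win_b$meth_reads + win_b$unmeth_reads
  out <- data.frame(
    gene_id = win_a$gene_id,
    window_index = win_a$window_index,
    context = win_a$context,
    comparison = comparison,
    meth_A = win_a$meth_reads, unmeth_A = win_a$unmeth_reads,
    meth_B = win_b$meth_reads, unmeth_B = win_b$unmeth_reads,
    pct_A = win_a$mean_pct, pct_B = win_b$mean_pct,
    stringsAsFactors = FALSE
  )
  out$delta_pct <- out$pct_B - out$pct_A
  out$p_value <- NA_real_
  callable <- cov_a > 0L & cov_b > 0L
  out$p_value[callable] <- fisher_exact_two_tailed(
    out$meth_A[callable], out$unmeth_A[callable],
    out$meth_B[callable], out$unmeth_B[callable])
  out$p_adj_BH <- NA_real_
  for (cx in unique(out$context)) {
    sel <- out$context == cx & callable
    out$p_adj_BH[sel] <- stats::p.adjust(out$p_value[sel], method = "BH")
  }
  out$no_call <- !callable
  out$is_dmr <- ifelse(callable,
                       out$p_value < alpha & abs(out$delta_pct) > delta_threshold,
                       NA)
  attr(out, "alpha") <- alpha
  attr(out, "delta_threshold") <- delta_threshold
  out
}

#' Summarize DMR calls into gene-level DMG status
#'
#' A gene is differentially methylated in a context iff it holds at least one
#' DMR window in that context, and a DMG overall iff it is differentially
#' methylated in at least one of CpG, CHG, CHH (the pooled `"all"` track is
#' reported separately and does not enter `is_dmg_any`).
#'
#' @param calls Output of [call_dmrs()].
#' @return `data.frame` per gene with per-context DMR window counts, per
#'   context DMG flags and `is_dmg_any`; the run-level DMG fraction is
#'   attached as attribute `dmg_any_fraction`.
#' @export
summarize_dmgs <- function(calls) {
  genes <- sort(unique(calls$gene_id))
  contexts <- c("CpG", "CHG", "CHH", "all")
  hits <- ifelse(is.na(calls$is_dmr), 0L, as.integer(calls$is_dmr))
  n_dmr <- tapply(hits, list(factor(calls$gene_id, levels = genes),
                             factor(calls$context, levels = contexts)),
                  sum, default = 0L)
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (cx in contexts) out[[paste0("n_dmr_", cx)]] <- as.integer(n_dmr[, cx])
  for (cx in contexts) out[[paste0("is_dmg_", cx)]] <- n_dmr[, cx] > 0
  out$is_dmg_any <- out$is_dmg_CpG | out$is_dmg_CHG | out$is_dmg_CHH
  attr(out, "dmg_any_fraction") <- mean(out$is_dmg_any)
  out
}

#' TSS-anchored metaprofile
#'
#' The average methylation curve along the region: per window, the mean over
#' genes of each replicate's window methylation percentage, then the mean
#' over replicates. Windows without coverage in a gene are excluded from that
#' gene's contribution, never counted as zero.
#'
#' @param window_stats_by_sample Named list (one element per replicate
#'   sample) of [aggregate_window_counts()] outputs.
#' @param context `"all"` for the global curve, or one of CpG/CHG/CHH.
#' @return `data.frame` with `window_index`, `mean_pct` (over replicates),
#'   `n_replicates`.
#' @export
metaprofile <- function(window_stats_by_sample, context = "all") {
  stopifnot(length(window_stats_by_sample) >= 1L)
  per_rep <- lapply(window_stats_by_sample, function(ws) {
    ws <- ws[ws$context == context, , drop = FALSE]
    tapply(ws$mean_pct, ws$window_index, mean, na.rm = TRUE)
  })
  idx <- sort(as.integer(names(per_rep[[1L]])))
  mat <- vapply(per_rep, function(v) as.numeric(v[as.character(idx)]),
                numeric(length(idx)))
  mat <- matrix(mat, nrow = length(idx))
  mat[is.nan(mat)] <- NA_real_
  data.frame(
    window_index = idx,
    mean_pct = rowMeans(mat, na.rm = TRUE),
    n_replicates = rowSums(!is.na(mat))
  )
}

#' Export windows as BED intervals
#'
#' Window coordinates against the region mini-contigs, 0-based half-open.
#'
#' @param genes Character vector of gene IDs.
#' @param region_length,window_size Tiling geometry.
#' @return `data.frame` in BED3+1 layout (`chrom`, `start`, `end`, `name`).
#' @export
windows_as_bed <- function(genes, region_length = 3000L, window_size = 50L) {
  tiles <- tile_windows(region_length, window_size)
  out <- do.call(rbind, lapply(genes, function(g)
    data.frame(chrom = g, start = tiles$start, end = tiles$end,
               name = paste0(g, "_w", tiles$window_index),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
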