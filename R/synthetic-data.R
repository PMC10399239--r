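#' Simulation configuration
#'
#' Parameters of the synthetic targeted-bisulfite dataset. The generator
#' emulates a 2-condition (cool 18 C / warm 28 C) x 2-embryo-part
#' (apical/basal) factorial with three replicates of pooled material per
#' cell: context-specific base methylation (CpG high, CHG intermediate,
#' CHH low), a promoter profile declining toward the TSS with a low gene
#' body, multiplicative hypermethylation of the warm condition, an optional
#' extra factor for the warm-basal cell, and planted window-level
#' differences for recovery testing.
#'
#' @param n_genes Number of target genes.
#' @param region_length,tss_offset Region geometry (defaults 3000 / 2000).
#' @param gc_content GC fraction of the i.i.d. simulated sequences.
#' @param base_level Named fractions per context; defaults CpG 0.35,
#'   CHG 0.12, CHH 0.03.
#' @param promoter_profile `"linear_decline"` or `"constant"`.
#' @param promoter_start_mult,promoter_end_mult Spatial multipliers at the
#'   promoter start and at the TSS for the linear decline.
#' @param body_level_multiplier Constant spatial multiplier over the body.
#' @param condition_effect Multiplicative hypermethylation of the warm
#'   condition (default 1.4).
#' @param part_effect Extra multiplicative factor for warm-basal samples
#'   (default 1.2; set 1 to disable).
#' @param conversion_failure Bisulfite conversion failure rate folded into
#'   the per-site probability (default 0).
#' @param planted_dmrs `data.frame(gene_id, window_index, context, delta)`
#'   of true differences added (pre-clipping) to the warm condition, or
#'   `NULL`.
#' @param mean_coverage Expected reads per site per replicate (default 30).
#' @param coverage_model `"poisson"` or `"fixed"`.
#' @param n_replicates Replicates per condition x part cell (default 3).
#' @param window_size Window width used to resolve planted windows.
#' @param seed Integer seed; fully determines the generated bundle.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 200L,
                       region_length = 3000L,
                       tss_offset = 2000L,
                       gc_content = 0.4,
                       base_level = c(CpG = 0.35, CHG = 0.12, CHH = 0.03),
                       promoter_profile = c("linear_decline", "constant"),
                       promoter_start_mult = 1.0,
                       promoter_end_mult = 0.3,
                       body_level_multiplier = 0.25,
                       condition_effect = 1.4,
                       part_effect = 1.2,
                       conversion_failure = 0,
                       planted_dmrs = NULL,
                       mean_coverage = 30,
                       coverage_model = c("poisson", "fixed"),
                       n_replicates = 3L,
                       window_size = 50L,
                       seed = 1L) {
  promoter_profile <- match.arg(promoter_profile)
  coverage_model <- match.arg(coverage_model)
  if (gc_content < 0 || gc_content > 1) stop("gc_content must be in [0, 1]")
  if (any(base_level < 0 | base_level > 1))
    stop("base_level fractions must be in [0, 1]")
  if (!all(c("CpG", "CHG", "CHH") %in% names(base_level)))
    stop("base_level must name CpG, CHG and CHH")
  if (region_length %% window_size != 0L)
    stop("window_size must divide region_length")
  if (!is.null(planted_dmrs)) {
    need <- c("gene_id", "window_index", "context", "delta")
    if (!all(need %in% names(planted_dmrs)))
      stop("planted_dmrs needs columns: ", paste(need, collapse = ", "))
    if (any(planted_dmrs$window_index < 0) ||
        any(planted_dmrs$window_index >= region_length %/% window_size))
      stop("planted_dmrs reference windows outside the region")
  }
  structure(list(
    n_genes = as.integer(n_genes), region_length = as.integer(region_length),
    tss_offset = as.integer(tss_offset), gc_content = gc_content,
    base_level = base_level, promoter_profile = promoter_profile,
    promoter_start_mult = promoter_start_mult,
    promoter_end_mult = promoter_end_mult,
    body_level_multiplier = body_level_multiplier,
    condition_effect = condition_effect, part_effect = part_effect,
    conversion_failure = conversion_failure, planted_dmrs = planted_dmrs,
    mean_coverage = mean_coverage, coverage_model = coverage_model,
    n_replicates = as.integer(n_replicates),
    window_size = as.integer(window_size), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate target-region sequences
#'
#' I.i.d. bases at the configured GC content (G and C equiprobable, A and T
#' equiprobable); deterministic under the config seed when called through
#' [simulate_bundle()].
#'
#' @param config A [sim_config()].
#' @return Named list of [target_region] objects (`gene_001`, ...).
#' @export
simulate_sequences <- function(config) {
  p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
         G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  regions <- lapply(seq_len(config$n_genes), function(i) {
    s <- paste(sample(names(p), config$region_length, replace = TRUE,
                      prob = p), collapse = "")
    target_region(sprintf("gene_%03d", i), s, config$tss_offset)
  })
  names(regions) <- vapply(regions, `[[`, "", "gene_id")
  regions
}

.spatial_multiplier <- function(config, position) {
  in_prom <- position < config$tss_offset
  if (config$promoter_profile == "constant") {
    prom <- rep(config$promoter_start_mult, length(position))
  } else {
    frac <- position / (config$tss_offset - 1L)  # 0 at start, 1 at TSS-1
    prom <- config$promoter_start_mult +
      frac * (config$promoter_end_mult - config$promoter_start_mult)
  }
  ifelse(in_prom, prom, config$body_level_multiplier)
}

.group_factor <- function(config, condition, part) {
  f <- if (condition == "warm") config$condition_effect else 1
  if (condition == "warm" && part == "basal") f <- f * config$part_effect
  f
}

#' True methylation probability surface
#'
#' `p = base_level[context] * spatial(position) * group factor`, clipped to
#' `[0, 1]`, with planted DMR deltas added (pre-clipping) to warm-condition
#' samples in their window and context, and the conversion-failure rate
#' folded in as `p + (1 - p) * failure`.
#'
#' @param config A [sim_config()].
#' @param sites Site table from [enumerate_sites_all()] (ambiguous rows get
#'   `NA`).
#' @param condition `"cool"` or `"warm"`.
#' @param part `"apical"` or `"basal"`.
#' @return Numeric vector of probabilities aligned with `sites` rows.
#' @export
methylation_surface <- function(config, sites, condition, part) {
  unamb <- sites$context %in% c("CpG", "CHG", "CHH")
  p <- rep(NA_real_, nrow(sites))
  base <- unname(config$base_level[sites$context[unamb]])
  p[unamb] <- base * .spatial_multiplier(config, sites$position[unamb]) *
    .group_factor(config, condition, part)
  if (!is.null(config$planted_dmrs) && condition == "warm") {
    win <- sites$position %/% config$window_size
    pk <- paste(config$planted_dmrs$gene_id, config$planted_dmrs$window_index,
                config$planted_dmrs$context, sep = "\r")
    m <- match(paste(sites$gene_id, win, sites$context, sep = "\r"), pk)
    hit <- !is.na(m)
    p[hit] <- p[hit] + config$planted_dmrs$delta[m[hit]]
  }
  if (config$conversion_failure > 0)
    p <- p + (1 - p) * config$conversion_failure
  pmin(pmax(p, 0), 1)
}

#' Generate a complete synthetic input bundle
#'
#' Simulates sequences, per-site true methylation surfaces and per-replicate
#' read counts for the full factorial design, and (optionally) writes the
#' bundle in exactly the formats the pipeline reads: FASTA, region table,
#' one CX report per sample, sample manifest, ground-truth table and planted
#' DMR registry, plus the resolved configuration as YAML. The seed fully
#' determines the output.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory, or `NULL` to return in memory only.
#' @return Invisible list with `regions`, `sites`, `manifest`, `counts`
#'   (named list of per-sample count tables), `truth` (per-site true p per
#'   group) and written `paths` (when `outdir` is given).
#' @export
simulate_bundle <- function(config, outdir = NULL) {
  set.seed(config$seed)
  regions <- simulate_sequences(config)
  sites <- enumerate_sites_all(regions)
  rownames(sites) <- NULL

  groups <- expand.grid(part = c("apical", "basal"),
                        condition = c("cool", "warm"),
                        stringsAsFactors = FALSE)[, c("condition", "part")]
  surfaces <- lapply(seq_len(nrow(groups)), function(i)
    methylation_surface(config, sites, groups$condition[i], groups$part[i]))
  names(surfaces) <- paste(groups$condition, groups$part, sep = "_")

  unamb <- sites$context %in% c("CpG", "CHG", "CHH")
  man <- NULL
  counts <- list()
  for (i in seq_len(nrow(groups))) {
    for (r in seq_len(config$n_replicates)) {
      sid <- sprintf("%s_%s_r%d", groups$condition[i], groups$part[i], r)
      n <- sum(unamb)
      cov <- switch(config$coverage_model,
                    poisson = stats::rpois(n, config$mean_coverage),
                    fixed = rep(as.integer(round(config$mean_coverage)), n))
      meth <- stats::rbinom(n, cov, surfaces[[i]][unamb])
      cnt <- data.frame(
        gene_id = sites$gene_id[unamb], position = sites$position[unamb],
        strand = sites$strand[unamb], meth_reads = meth,
        unmeth_reads = cov - meth, stringsAsFactors = FALSE
      )
      counts[[sid]] <- cnt
      man <- rbind(man, data.frame(
        sample_id = sid, condition = groups$condition[i],
        part = groups$part[i], replicate = r,
        counts_path = paste0(sid, ".cx.tsv"), stringsAsFactors = FALSE))
    }
  }

  truth <- sites
  for (g in names(surfaces)) truth[[paste0("p_", g)]] <- surfaces[[g]]

  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fasta <- file.path(outdir, "regions.fasta")
    seqs <- Biostrings::DNAStringSet(vapply(regions, `[[`, "", "sequence"))
    names(seqs) <- names(regions)
    Biostrings::writeXStringSet(seqs, fasta, width = 80L)
    region_table <- file.path(outdir, "regions.tsv")
    utils::write.table(
      data.frame(gene_id = names(regions),
                 length = vapply(regions, `[[`, 0L, "length"),
                 tss_offset = vapply(regions, `[[`, 0L, "tss_offset")),
      region_table, sep = "\t", quote = FALSE, row.names = FALSE)
    for (sid in names(counts))
      write_cx_report(counts[[sid]], file.path(outdir, paste0(sid, ".cx.tsv")),
                      sites = sites)
    manifest <- file.path(outdir, "manifest.tsv")
    utils::write.table(man, manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth_path <- file.path(outdir, "ground_truth.tsv")
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    planted_path <- NULL
    if (!is.null(config$planted_dmrs)) {
      planted_path <- file.path(outdir, "planted_dmrs.tsv")
      utils::write.table(config$planted_dmrs, planted_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    cfg_path <- file.path(outdir, "sim_config.yaml")
    cfg <- unclass(config)
    cfg$base_level <- as.list(cfg$base_level)
    if (!is.null(cfg$planted_dmrs))
      cfg$planted_dmrs <- lapply(cfg$planted_dmrs, I)
    yaml::write_yaml(cfg, cfg_path)
    paths <- list(fasta = fasta, region_table = region_table,
                  manifest = manifest, ground_truth = truth_path,
                  planted_dmrs = planted_path, config = cfg_path)
  }
  invisible(list(regions = regions, sites = sites, manifest = man,
                 counts = counts, truth = truth, paths = paths,
                 config = config))
}
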