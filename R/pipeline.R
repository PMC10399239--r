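#' Pipeline run configuration
#'
#' Bundles all paths, thresholds and mode switches of one analysis run.
#' Every parameter is echoed into the comment header of every output table
#' so results are self-describing. Unknown keys are rejected.
#'
#' @param fasta,region_table,manifest Input paths (see
#'   [read_target_regions()], [read_manifest()]).
#' @param outdir Output directory for result tables.
#' @param window_size Window width in nt (default 50).
#' @param alpha Raw p-value threshold for DMR calls (default 0.05).
#' @param delta_threshold DMR effect threshold in percentage points
#'   (default 20; the inequality is strict).
#' @param min_coverage Per-site interrogation threshold (default 1).
#' @param context_mode `"weighted"` or `"literal"` per-context mean.
#' @param denominator_mode `"union"` or `"either_group_mean"` for shared
#'   percentages.
#' @param count_level `"reads"` (pooled read counts enter the Fisher table)
#'   or `"sites"` (each interrogated site contributes one methylated or
#'   unmethylated unit per its classification).
#' @param comparisons Which comparison families to run.
#' @param seed Recorded in output headers (the pipeline itself is
#'   deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(fasta, region_table, manifest, outdir,
                       window_size = 50L, alpha = 0.05,
                       delta_threshold = 20, min_coverage = 1L,
                       context_mode = c("weighted", "literal"),
                       denominator_mode = c("union", "either_group_mean"),
                       count_level = c("reads", "sites"),
                       comparisons = c("conditions_within_part",
                                       "parts_within_condition"),
                       seed = NA_integer_) {
  context_mode <- match.arg(context_mode)
  denominator_mode <- match.arg(denominator_mode)
  count_level <- match.arg(count_level)
  comparisons <- match.arg(comparisons, several.ok = TRUE)
  structure(list(
    fasta = fasta, region_table = region_table, manifest = manifest,
    outdir = outdir, window_size = as.integer(window_size), alpha = alpha,
    delta_threshold = delta_threshold, min_coverage = as.integer(min_coverage),
    context_mode = context_mode, denominator_mode = denominator_mode,
    count_level = count_level, comparisons = comparisons, seed = seed
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys are [run_config()] arguments; unknown
#'   keys are rejected.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

.config_header <- function(config) {
  c(list(package = paste0("methwindow ",
                          as.character(utils::packageVersion("methwindow")))),
    lapply(config[c("window_size", "alpha", "delta_threshold", "min_coverage",
                    "context_mode", "denominator_mode", "count_level",
                    "seed")], identity))
}

# Convert pooled read counts to site-level unit counts for the
# count_level = "sites" mode: one methylated or unmethylated observation per
# interrogated site.
.site_level_counts <- function(classified) {
  keep <- classified$state != "uninterrogated"
  out <- classified[keep, , drop = FALSE]
  out$meth_reads <- as.integer(out$state == "methylated")
  out$unmeth_reads <- as.integer(out$state == "unmethylated")
  out
}

#' Run the complete analysis pipeline
#'
#' Executes every stage over every configured comparison: site enumeration
#' and context classification, per-group gene methylation summaries, the
#' methylated/unmethylated context decomposition, shared-state percentages,
#' 50-bp window aggregation, metaprofiles, DMR calling and DMG
#' summarization. Inputs are checked for mutual consistency before any
#' computation. All result tables are written to `config$outdir` with
#' self-describing headers.
#'
#' @param config A [run_config()].
#' @return Invisible `methwindow_run` object: a list of all result tables
#'   plus `files`, the manifest of written paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$fasta, config$region_table, config$manifest))
    if (!file.exists(p)) stop("input not found: ", p)
  regions <- read_target_regions(config$fasta, config$region_table)
  man <- read_manifest(config$manifest)
  missing <- !file.exists(man$counts_path)
  if (any(missing))
    stop("counts file not found for sample ", man$sample_id[missing][1L],
         ": ", man$counts_path[missing][1L])
  lens <- unique(vapply(regions, `[[`, 0L, "length"))
  if (length(lens) != 1L)
    stop("all regions must share one length; found: ",
         paste(lens, collapse = ", "))
  L <- lens
  sites <- enumerate_sites_all(regions)
  rownames(sites) <- NULL

  annotated <- lapply(seq_len(nrow(man)), function(i) {
    cnt <- read_cx_report(man$counts_path[i])
    bad <- setdiff(unique(cnt$gene_id), names(regions))
    if (length(bad))
      stop(sprintf("sample %s reports gene %s absent from FASTA",
                   man$sample_id[i], bad[1L]))
    annotate_counts(cnt, sites)
  })
  names(annotated) <- man$sample_id

  group_key <- paste(man$condition, man$part, sep = "_")
  groups <- unique(group_key)
  pooled <- lapply(groups, function(g)
    pool_counts(annotated[group_key == g]))
  names(pooled) <- groups
  classified <- lapply(pooled, classify_sites, min_coverage = config$min_coverage)

  # gene-level methylation per pooled group
  gene_tabs <- do.call(rbind, lapply(groups, function(g) {
    tab <- gene_methylation_table(pooled[[g]], scope = "both",
                                  min_coverage = config$min_coverage,
                                  context_mode = config$context_mode)
    cbind(group = g, tab, stringsAsFactors = FALSE)
  }))

  # context decomposition per group and region
  decomp <- do.call(rbind, lapply(groups, function(g)
    do.call(rbind, lapply(c("promoter", "body"), function(sc) {
      d <- context_fraction_decomposition(classified[[g]], scope = sc,
                                          min_coverage = config$min_coverage,
                                          context_mode = config$context_mode)
      if (is.null(d)) return(NULL)
      cbind(group = g, scope = sc, d, stringsAsFactors = FALSE)
    }))))

  comparison_pairs <- list()
  if ("conditions_within_part" %in% config$comparisons)
    for (pt in c("apical", "basal"))
      comparison_pairs[[sprintf("warm_vs_cool_%s", pt)]] <-
        c(paste0("cool_", pt), paste0("warm_", pt))
  if ("parts_within_condition" %in% config$comparisons)
    for (cd in c("cool", "warm"))
      comparison_pairs[[sprintf("basal_vs_apical_%s", cd)]] <-
        c(paste0(cd, "_apical"), paste0(cd, "_basal"))
  comparison_pairs <- Filter(function(pr) all(pr %in% groups),
                             comparison_pairs)

  shared <- do.call(rbind, lapply(names(comparison_pairs), function(nm) {
    pr <- comparison_pairs[[nm]]
    do.call(rbind, lapply(c("promoter", "body"), function(sc)
      do.call(rbind, lapply(c("CpG", "CHG", "CHH"), function(cx)
        cbind(comparison = nm,
              shared_context_percentages(classified[[pr[1L]]],
                                         classified[[pr[2L]]], cx, sc,
                                         config$denominator_mode),
              stringsAsFactors = FALSE)))))
  }))

  # windows: per sample (metaprofiles) and per pooled group (DMR tests)
  win_by_sample <- lapply(annotated, aggregate_window_counts,
                          region_length = L,
                          window_size = config$window_size,
                          min_coverage = config$min_coverage)
  dmr_input <- if (config$count_level == "reads") pooled
               else lapply(classified, .site_level_counts)
  win_by_group <- lapply(dmr_input, aggregate_window_counts,
                         region_length = L,
                         window_size = config$window_size,
                         min_coverage = if (config$count_level == "reads")
                           config$min_coverage else 1L)

  meta <- do.call(rbind, lapply(groups, function(g)
    do.call(rbind, lapply(c("all", "CpG", "CHG", "CHH"), function(cx)
      cbind(group = g, context = cx,
            metaprofile(win_by_sample[group_key == g], cx),
            stringsAsFactors = FALSE)))))

  calls <- do.call(rbind, lapply(names(comparison_pairs), function(nm) {
    pr <- comparison_pairs[[nm]]
    call_dmrs(win_by_group[[pr[1L]]], win_by_group[[pr[2L]]],
              alpha = config$alpha, delta_threshold = config$delta_threshold,
              comparison = nm)
  }))
  tiles <- tile_windows(L, config$window_size)
  calls$window_start <- tiles$start[calls$window_index + 1L]
  calls$window_end <- tiles$end[calls$window_index + 1L]

  dmg <- do.call(rbind, lapply(names(comparison_pairs), function(nm)
    cbind(comparison = nm,
          summarize_dmgs(calls[calls$comparison == nm, , drop = FALSE]),
          stringsAsFactors = FALSE)))

  hdr <- .config_header(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(f) file.path(config$outdir, f)
  files <- c(
    gene_methylation = write_result_table(gene_tabs,
      out_path("gene_methylation.tsv"), hdr),
    context_decomposition = write_result_table(decomp,
      out_path("context_decomposition.tsv"), hdr),
    shared_contexts = write_result_table(shared,
      out_path("shared_contexts.tsv"), hdr),
    metaprofile = write_result_table(meta, out_path("metaprofile.tsv"), hdr),
    dmr_calls = write_result_table(
      calls[, c("gene_id", "window_index", "window_start", "window_end",
                "context", "comparison", "meth_A", "unmeth_A", "meth_B",
                "unmeth_B", "pct_A", "pct_B", "delta_pct", "p_value",
                "p_adj_BH", "no_call", "is_dmr")],
      out_path("dmr_calls.tsv"), hdr),
    dmg_summary = write_result_table(dmg, out_path("dmg_summary.tsv"), hdr),
    windows_bed = {
      bed <- windows_as_bed(names(regions), L, config$window_size)
      utils::write.table(bed, out_path("windows.bed"), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
      out_path("windows.bed")
    }
  )

  res <- structure(list(
    config = config, regions = regions, sites = sites, manifest = man,
    groups = groups, gene_methylation = gene_tabs,
    context_decomposition = decomp, shared_contexts = shared,
    metaprofile = meta, dmr_calls = calls, dmg_summary = dmg,
    win_by_group = win_by_group, files = files
  ), class = "methwindow_run")
  invisible(res)
}

#' @export
print.methwindow_run <- function(x, ...) {
  n_dmr <- sum(x$dmr_calls$is_dmr, na.rm = TRUE)
  cat(sprintf("<methwindow_run> %d genes, %d samples, %d groups\n",
              length(x$regions), nrow(x$manifest), length(x$groups)))
  cat(sprintf("  DMR windows called: %d (alpha=%g, delta>%g points)\n",
              n_dmr, x$config$alpha, x$config$delta_threshold))
  for (nm in unique(x$dmg_summary$comparison)) {
    d <- x$dmg_summary[x$dmg_summary$comparison == nm, ]
    cat(sprintf("  %s: %d/%d genes DMG in >=1 context (%.1f%%)\n", nm,
                sum(d$is_dmg_any), nrow(d), 100 * mean(d$is_dmg_any)))
  }
  cat("  outputs:", dirname(x$files[[1L]]), "\n")
  invisible(x)
}

#' Render a plain-text and figure report from pipeline outputs
#'
#' Reads only the written TSVs (single source of truth) and produces
#' `report.txt` plus PNG figures: per-context metaprofile curves per group,
#' context-decomposition bars and DMG fractions per comparison. Missing
#' tables are listed in the report, which is still produced.
#'
#' @param outdir Directory holding the pipeline outputs.
#' @return Invisible character vector of written report files.
#' @export
render_report <- function(outdir) {
  want <- c("gene_methylation.tsv", "context_decomposition.tsv",
            "shared_contexts.tsv", "metaprofile.tsv", "dmr_calls.tsv",
            "dmg_summary.tsv")
  have <- file.exists(file.path(outdir, want))
  tabs <- lapply(file.path(outdir, want[have]), read_result_table)
  names(tabs) <- sub("[.]tsv$", "", want[have])
  written <- character()

  lines <- c("methwindow run report", strrep("=", 21), "")
  if (any(!have))
    lines <- c(lines, paste("MISSING TABLES:", paste(want[!have],
                                                     collapse = ", ")), "")
  grp_col <- c(cool_apical = "#4477c9", cool_basal = "#1b3f8f",
               warm_apical = "#e98383", warm_basal = "#c02626")

  if (!is.null(tabs$metaprofile)) {
    mp <- tabs$metaprofile
    for (cx in unique(mp$context)) {
      f <- file.path(outdir, sprintf("metaprofile_%s.png", cx))
      grDevices::png(f, width = 800, height = 500)
      sub <- mp[mp$context == cx, ]
      graphics::plot(NA, xlim = range(sub$window_index),
                     ylim = c(0, max(sub$mean_pct, na.rm = TRUE) * 1.1),
                     xlab = "50-bp window", ylab = "mean methylation (%)",
                     main = sprintf("Metaprofile (%s)", cx))
      for (g in unique(sub$group)) {
        s <- sub[sub$group == g, ]
        graphics::lines(s$window_index, s$mean_pct,
                        col = if (g %in% names(grp_col)) grp_col[[g]] else "grey40",
                        lwd = 2)
      }
      tss <- max(mp$window_index) * 2 / 3 + 2 / 3  # informative only
      graphics::abline(v = tss, lty = 3)
      graphics::legend("topright", legend = unique(sub$group),
                       col = grp_col[unique(sub$group)], lwd = 2, bty = "n")
      grDevices::dev.off()
      written <- c(written, f)
    }
    lines <- c(lines, sprintf("Metaprofiles: %d contexts x %d groups rendered.",
                              length(unique(mp$context)),
                              length(unique(mp$group))), "")
  }

  if (!is.null(tabs$context_decomposition)) {
    d <- tabs$context_decomposition
    f <- file.path(outdir, "context_decomposition.png")
    grDevices::png(f, width = 900, height = 500)
    graphics::par(mfrow = c(1, 2))
    for (what in c("pct_of_unmethylated", "pct_of_methylated")) {
      key <- paste(d$group, d$scope)
      m <- tapply(d[[what]], list(d$context, key), identity)
      graphics::barplot(as.matrix(m), beside = FALSE, las = 2,
                        col = c("#888888", "#bbaa44", "#336633"),
                        main = sub("pct_of_", "", what),
                        ylab = "% of sites")
    }
    grDevices::dev.off()
    written <- c(written, f)
    lines <- c(lines, "Context decomposition (per group, scope):",
               utils::capture.output(print(
                 d[, c("group", "scope", "context", "pct_of_unmethylated",
                       "pct_of_methylated", "mean_methylation_pct")],
                 row.names = FALSE)), "")
  }

  if (!is.null(tabs$dmg_summary)) {
    g <- tabs$dmg_summary
    frac <- tapply(g$is_dmg_any == "TRUE" | g$is_dmg_any == TRUE,
                   g$comparison, mean)
    f <- file.path(outdir, "dmg_fractions.png")
    grDevices::png(f, width = 700, height = 450)
    graphics::barplot(100 * frac, ylab = "% genes DMG (>=1 context)",
                      las = 2, col = "#44688f",
                      main = "DMG fraction per comparison")
    grDevices::dev.off()
    written <- c(written, f)
    lines <- c(lines, "DMG fraction per comparison:",
               sprintf("  %s: %.1f%% (%d/%d genes)", names(frac), 100 * frac,
                       round(frac * tapply(g$gene_id, g$comparison, length)),
                       tapply(g$gene_id, g$comparison, length)), "")
  }

  if (!is.null(tabs$dmr_calls)) {
    dc <- tabs$dmr_calls
    n_dmr <- sum(dc$is_dmr == "TRUE" | dc$is_dmr == TRUE, na.rm = TRUE)
    lines <- c(lines,
               if (n_dmr == 0) "DMR windows called: zero."
               else sprintf("DMR windows called: %d of %d tested.", n_dmr,
                            sum(!(dc$no_call == "TRUE" | dc$no_call == TRUE))),
               "")
  }

  report <- file.path(outdir, "report.txt")
  writeLines(lines, report)
  invisible(c(report, written))
}
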