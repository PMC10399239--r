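#' Annotate counts with context and region labels
#'
#' Joins per-site counts to the enumerated sites of the target regions,
#' attaching `context` and `region_label`. Every counted position must be an
#' enumerated cytosine site of its gene; a mismatch means the report and the
#' FASTA disagree and is a hard error. Ambiguous-context sites are kept here
#' (flagged) and excluded by the downstream statistics.
#'
#' @param counts `data.frame` from [read_cx_report()].
#' @param sites `data.frame` from [enumerate_sites_all()].
#' @return `counts` with `context` and `region_label` columns added.
#' @export
annotate_counts <- function(counts, sites) {
  m <- match(paste(counts$gene_id, counts$position, counts$strand),
             paste(sites$gene_id, sites$position, sites$strand))
  if (anyNA(m)) {
    i <- which(is.na(m))[1L]
    stop(sprintf(
      "counts/sequence mismatch: %s position %d strand %s is not a cytosine site",
      counts$gene_id[i], counts$position[i], counts$strand[i]))
  }
  counts$context <- sites$context[m]
  counts$region_label <- sites$region_label[m]
  counts
}

#' Pool replicate counts within a group
#'
#' Sums methylated and unmethylated read counts per site across the given
#' samples. Used both for group-level site classification and for the pooled
#' Fisher test counts.
#'
#' @param annotated_list List of annotated count tables (one per sample).
#' @return One annotated count table with summed `meth_reads`/`unmeth_reads`.
#' @export
pool_counts <- function(annotated_list) {
  all <- do.call(rbind, annotated_list)
  key <- paste(all$gene_id, all$position, all$strand, sep = "\r")
  sums <- rowsum(cbind(meth = all$meth_reads, unmeth = all$unmeth_reads),
                 group = key, reorder = FALSE)
  first <- !duplicated(key)
  out <- all[first, c("gene_id", "position", "strand", "context",
                      "region_label"), drop = FALSE]
  m <- match(key[first], rownames(sums))
  out$meth_reads <- as.integer(sums[m, "meth"])
  out$unmeth_reads <- as.integer(sums[m, "unmeth"])
  out <- out[order(out$gene_id, out$position,
                   match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-site methylation fraction
#'
#' The fraction of reads methylated at one site: `meth / (meth + unmeth)`.
#' Sites with coverage below `min_coverage` are not interrogated and return
#' `NA` (missing is a value here, never an error).
#'
#' @param meth_reads,unmeth_reads Non-negative integer vectors.
#' @param min_coverage Minimum total reads for a site to count as
#'   interrogated (default 1).
#' @return Numeric vector of fractions in `[0, 1]`, `NA` where uncovered.
#' @export
site_methylation_fraction <- function(meth_reads, unmeth_reads,
                                      min_coverage = 1L) {
  cov <- meth_reads + unmeth_reads
  ifelse(cov >= min_coverage & cov > 0L, meth_reads / cov, NA_real_)
}

.scope_filter <- function(df, scope = c("both", "promoter", "body")) {
  scope <- match.arg(scope)
  df <- df[df$context %in% c("CpG", "CHG", "CHH"), , drop = FALSE]
  if (scope != "both") df <- df[df$region_label == scope, , drop = FALSE]
  df
}

#' Gene-level mean methylation (read-weighted)
#'
#' Total methylated cytosine reads divided by total reads over all
#' interrogated sites in scope, as a percentage: the per-gene average taken
#' over all reads rather than over sites, so deeply covered sites weigh more.
#'
#' @param annotated Annotated counts for one gene (or any stratum).
#' @param scope `"both"` (default), `"promoter"` or `"body"`.
#' @param min_coverage Interrogation threshold (default 1).
#' @return Percentage in `[0, 100]`, or `NA` if no site is interrogated.
#' @export
gene_mean_methylation <- function(annotated, scope = "both", min_coverage = 1L) {
  df <- .scope_filter(annotated, scope)
  cov <- df$meth_reads + df$unmeth_reads
  df <- df[cov >= min_coverage & cov > 0L, , drop = FALSE]
  if (nrow(df) == 0L) return(NA_real_)
  100 * sum(df$meth_reads) / sum(df$meth_reads + df$unmeth_reads)
}

#' Per-context mean methylation
#'
#' Two modes. `weighted` (default): read-weighted mean over interrogated
#' sites of the context — total methylated reads over total reads, x 100.
#' `literal`: total methylated cytosine observations in the context divided
#' by (total cytosine observations in the context x number of interrogated
#' context sites), x 100 — a double normalization retained for reproduction
#' of per-gene context indices computed that way; both modes coincide when
#' the context has exactly one site.
#'
#' @param annotated Annotated counts for one stratum.
#' @param context `"CpG"`, `"CHG"` or `"CHH"`.
#' @param mode `"weighted"` or `"literal"`.
#' @param scope Region scope (see [gene_mean_methylation()]).
#' @param min_coverage Interrogation threshold.
#' @return Percentage, or `NA` if no interrogated site in the context.
#' @export
context_mean_methylation <- function(annotated, context,
                                     mode = c("weighted", "literal"),
                                     scope = "both", min_coverage = 1L) {
  mode <- match.arg(mode)
  stopifnot(context %in% c("CpG", "CHG", "CHH"))
  df <- .scope_filter(annotated, scope)
  df <- df[df$context == context, , drop = FALSE]
  cov <- df$meth_reads + df$unmeth_reads
  df <- df[cov >= min_coverage & cov > 0L, , drop = FALSE]
  if (nrow(df) == 0L) return(NA_real_)
  total_obs <- sum(df$meth_reads + df$unmeth_reads)
  if (mode == "weighted") {
    100 * sum(df$meth_reads) / total_obs
  } else {
    100 * sum(df$meth_reads) / (total_obs * nrow(df))
  }
}

#' Gene methylation summary table
#'
#' Per-gene global and per-context mean methylation plus interrogated-site
#' counts for one sample or pooled group.
#'
#' @param annotated Annotated counts (possibly many genes).
#' @param scope Region scope.
#' @param min_coverage Interrogation threshold.
#' @param context_mode Mode passed to [context_mean_methylation()].
#' @return One row per gene with `global_mean_pct`, `<ctx>_mean_pct` and
#'   `n_sites_<ctx>` columns; contexts with no interrogated site are `NA`.
#' @export
gene_methylation_table <- function(annotated, scope = "both",
                                   min_coverage = 1L,
                                   context_mode = "weighted") {
  idx <- split(seq_len(nrow(annotated)), annotated$gene_id)
  rows <- lapply(names(idx), function(g) {
    df <- annotated[idx[[g]], , drop = FALSE]
    sdf <- .scope_filter(df, scope)
    cov <- sdf$meth_reads + sdf$unmeth_reads
    interr <- sdf[cov >= min_coverage & cov > 0L, , drop = FALSE]
    n <- table(factor(interr$context, levels = c("CpG", "CHG", "CHH")))
    data.frame(
      gene_id = g,
      global_mean_pct = gene_mean_methylation(df, scope, min_coverage),
      CpG_mean_pct = context_mean_methylation(df, "CpG", context_mode, scope,
                                              min_coverage),
      CHG_mean_pct = context_mean_methylation(df, "CHG", context_mode, scope,
                                              min_coverage),
      CHH_mean_pct = context_mean_methylation(df, "CHH", context_mode, scope,
                                              min_coverage),
      n_sites_CpG = as.integer(n[["CpG"]]),
      n_sites_CHG = as.integer(n[["CHG"]]),
      n_sites_CHH = as.integer(n[["CHH"]]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify sites as methylated, unmethylated or uninterrogated
#'
#' Operates on group-pooled counts: a site below the coverage threshold is
#' `uninterrogated`; otherwise it is `unmethylated` when its methylation
#' level is exactly zero and `methylated` when any methylated read was seen
#' (level > 0).
#'
#' @param pooled Pooled annotated counts (see [pool_counts()]).
#' @param min_coverage Interrogation threshold.
#' @return `pooled` with a `state` column added.
#' @export
classify_sites <- function(pooled, min_coverage = 1L) {
  cov <- pooled$meth_reads + pooled$unmeth_reads
  state <- rep("uninterrogated", nrow(pooled))
  state[cov >= min_coverage & cov > 0L & pooled$meth_reads == 0L] <- "unmethylated"
  state[cov >= min_coverage & cov > 0L & pooled$meth_reads > 0L] <- "methylated"
  pooled$state <- state
  pooled
}

#' Context decomposition of methylated and unmethylated sites
#'
#' Within one (group, region) stratum: the share of unmethylated sites
#' contributed by each context (summing to 100 across CpG, CHG, CHH), the
#' same for methylated sites, and the per-context mean methylation level.
#'
#' @param classified Output of [classify_sites()].
#' @param scope Region scope.
#' @param min_coverage Interrogation threshold.
#' @param context_mode Mode for the per-context mean.
#' @return One row per context with `pct_of_unmethylated`,
#'   `pct_of_methylated`, `mean_methylation_pct` and site counts; `NULL` if
#'   the stratum holds no interrogated site.
#' @export
context_fraction_decomposition <- function(classified, scope = "both",
                                           min_coverage = 1L,
                                           context_mode = "weighted") {
  df <- .scope_filter(classified, scope)
  df <- df[df$state != "uninterrogated", , drop = FALSE]
  if (nrow(df) == 0L) return(NULL)
  contexts <- c("CpG", "CHG", "CHH")
  n_un <- table(factor(df$context[df$state == "unmethylated"], levels = contexts))
  n_me <- table(factor(df$context[df$state == "methylated"], levels = contexts))
  share <- function(n) if (sum(n) == 0L) rep(NA_real_, length(n)) else 100 * as.integer(n) / sum(n)
  data.frame(
    context = contexts,
    n_unmethylated = as.integer(n_un),
    n_methylated = as.integer(n_me),
    pct_of_unmethylated = share(n_un),
    pct_of_methylated = share(n_me),
    mean_methylation_pct = vapply(contexts, function(cx)
      context_mean_methylation(classified, cx, context_mode, scope,
                               min_coverage), numeric(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Shared methylation states between two groups
#'
#' For one context and region scope, the percentage of sites methylated in
#' both groups and unmethylated in both groups. Sites uninterrogated in
#' either group are excluded entirely. `union` mode (default) divides the
#' intersection by the union of the two groups' methylated (respectively
#' unmethylated) site sets; `either_group_mean` divides by the mean of the
#' two groups' totals.
#'
#' @param class_a,class_b Outputs of [classify_sites()] for the two groups.
#' @param context Context to compare.
#' @param scope Region scope.
#' @param denominator_mode `"union"` or `"either_group_mean"`.
#' @return One-row `data.frame` with `pct_shared_unmethylated`,
#'   `pct_shared_methylated` and the underlying site tallies; percentages are
#'   `NA` when the denominator is empty.
#' @export
shared_context_percentages <- function(class_a, class_b, context,
                                       scope = "both",
                                       denominator_mode = c("union",
                                                            "either_group_mean")) {
  denominator_mode <- match.arg(denominator_mode)
  stopifnot(context %in% c("CpG", "CHG", "CHH"))
  a <- .scope_filter(class_a, scope)
  b <- .scope_filter(class_b, scope)
  a <- a[a$context == context, , drop = FALSE]
  b <- b[b$context == context, , drop = FALSE]
  ka <- paste(a$gene_id, a$position, a$strand, sep = "\r")
  kb <- paste(b$gene_id, b$position, b$strand, sep = "\r")
  m <- match(ka, kb)
  ok <- !is.na(m) & a$state != "uninterrogated" &
    b$state[ifelse(is.na(m), 1L, m)] != "uninterrogated"
  sa <- a$state[ok]
  sb <- b$state[m[ok]]
  pct_for <- function(lab) {
    in_a <- sa == lab
    in_b <- sb == lab
    both <- sum(in_a & in_b)
    denom <- switch(denominator_mode,
                    union = sum(in_a | in_b),
                    either_group_mean = (sum(in_a) + sum(in_b)) / 2)
    if (denom == 0) NA_real_ else 100 * both / denom
  }
  data.frame(
    context = context, scope = scope, denominator_mode = denominator_mode,
    n_sites_compared = length(sa),
    pct_shared_unmethylated = pct_for("unmethylated"),
    pct_shared_methylated = pct_for("methylated"),
    stringsAsFactors = FALSE
  )
}
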