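#' Read a per-sample cytosine report
#'
#' Reads cytosine-level methylation counts in the Bismark cytosine-report
#' ("CX report") dialect: tab-separated, no header, columns `gene_id`,
#' 1-based `position`, `strand` (`+`/`-`), `count_methylated`,
#' `count_unmethylated`, and optional `context` and `trinucleotide` columns.
#' The optional columns are ignored: contexts are always recomputed from the
#' region sequence so the FASTA stays the single source of truth. Positions
#' are converted to the package's 0-based convention. Lines with zero total
#' coverage are retained (they are "not interrogated" and filtered
#' downstream). Gzip-compressed files are read transparently.
#'
#' @param path Path to the report (plain or `.gz`).
#' @return `data.frame` with columns `gene_id`, `position` (0-based),
#'   `strand`, `meth_reads`, `unmeth_reads`.
#' @export
read_cx_report <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L)
    return(data.frame(gene_id = character(), position = integer(),
                      strand = character(), meth_reads = integer(),
                      unmeth_reads = integer(), stringsAsFactors = FALSE))
  if (any(nf < 5L))
    stop(sprintf("malformed CX report '%s' at line %d: fewer than 5 fields",
                 path, which(nf < 5L)[1L]))
  if (length(unique(nf)) != 1L)
    stop(sprintf("malformed CX report '%s' at line %d: ragged field count",
                 path, which(nf != nf[1L])[1L]))
  cols <- c("character", "integer", "character", "integer", "integer",
            rep("NULL", nf[1L] - 5L))
  dat <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                      comment.char = "", colClasses = cols, fill = FALSE,
                      flush = TRUE, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("malformed CX report '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  if (nrow(dat) == 0L)
    return(data.frame(gene_id = character(), position = integer(),
                      strand = character(), meth_reads = integer(),
                      unmeth_reads = integer(), stringsAsFactors = FALSE))
  names(dat)[1:5] <- c("gene_id", "position", "strand", "meth_reads",
                       "unmeth_reads")
  bad <- which(is.na(dat$position) | is.na(dat$meth_reads) |
                 is.na(dat$unmeth_reads) | !dat$strand %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("malformed CX report '%s' at line %d", path, bad[1L]))
  neg <- which(dat$meth_reads < 0L | dat$unmeth_reads < 0L | dat$position < 1L)
  if (length(neg))
    stop(sprintf("negative count or non-positive position in '%s' at line %d",
                 path, neg[1L]))
  dat$position <- dat$position - 1L   # 1-based on disk, 0-based internally
  key <- paste(dat$gene_id, dat$position, dat$strand)
  if (anyDuplicated(key))
    stop(sprintf("duplicate (gene, position, strand) in '%s': %s",
                 path, key[duplicated(key)][1L]))
  dat[, c("gene_id", "position", "strand", "meth_reads", "unmeth_reads")]
}

#' Write a cytosine report
#'
#' Writes counts back to the CX-report dialect read by [read_cx_report()]
#' (1-based positions), sorted by gene, position, strand so reruns are
#' diffable. Context and trinucleotide columns are filled from `sites` when
#' given, else written as `.`.
#'
#' @param counts `data.frame` as returned by [read_cx_report()].
#' @param path Output path.
#' @param sites Optional site annotation from [enumerate_sites_all()] used to
#'   fill the context column.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(counts, path, sites = NULL) {
  counts <- counts[order(counts$gene_id, counts$position,
                         match(counts$strand, c("+", "-"))), , drop = FALSE]
  ctx <- rep(".", nrow(counts))
  if (!is.null(sites)) {
    m <- match(paste(counts$gene_id, counts$position, counts$strand),
               paste(sites$gene_id, sites$position, sites$strand))
    ctx <- ifelse(is.na(m), ".", sites$context[m])
  }
  out <- data.frame(counts$gene_id, counts$position + 1L, counts$strand,
                    counts$meth_reads, counts$unmeth_reads, ctx, ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' Tab-separated with header columns `sample_id`, `condition` (`cool`/`warm`),
#' `part` (`apical`/`basal`), `replicate`, `counts_path`. Validates the
#' factorial design and warns (without failing) when any condition x part
#' cell has fewer than `expected_replicates` samples.
#'
#' @param path Manifest path.
#' @param expected_replicates Replicates expected per cell (default 3, the
#'   pooled-embryo design).
#' @return `data.frame` of sample records; `counts_path` entries that are
#'   relative are resolved against the manifest's directory.
#' @export
read_manifest <- function(path, expected_replicates = 3L) {
  man <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("sample_id", "condition", "part", "replicate", "counts_path")
  if (!all(need %in% names(man)))
    stop("manifest must have header columns: ", paste(need, collapse = ", "))
  man$replicate <- as.integer(man$replicate)
  bad_cond <- setdiff(unique(man$condition), c("cool", "warm"))
  if (length(bad_cond))
    stop("unknown condition '", bad_cond[1L], "' (allowed: cool, warm)")
  bad_part <- setdiff(unique(man$part), c("apical", "basal"))
  if (length(bad_part))
    stop("unknown part '", bad_part[1L], "' (allowed: apical, basal)")
  if (anyDuplicated(man$sample_id))
    stop("duplicate sample_id: ", man$sample_id[duplicated(man$sample_id)][1L])
  key <- paste(man$condition, man$part, man$replicate)
  if (anyDuplicated(key))
    stop("duplicate (condition, part, replicate): ", key[duplicated(key)][1L])
  if (any(is.na(man$replicate)) || any(man$replicate < 1L))
    stop("replicate must be a positive integer")
  cells <- table(paste(man$condition, man$part))
  expected_cells <- as.vector(outer(c("cool", "warm"), c("apical", "basal"),
                                    paste))
  for (cell in expected_cells) {
    n <- if (cell %in% names(cells)) cells[[cell]] else 0L
    if (n < expected_replicates)
      warning(sprintf("design cell '%s' has %d replicate(s), expected %d",
                      cell, n, expected_replicates), call. = FALSE)
  }
  rel <- !grepl("^(/|[A-Za-z]:)", man$counts_path)
  man$counts_path[rel] <- file.path(dirname(path), man$counts_path[rel])
  man
}

#' Write a result table with a self-describing header
#'
#' All pipeline outputs carry `#`-prefixed comment lines recording the
#' configuration that produced them (min_coverage, modes, seed, thresholds),
#' then a header line and tab-separated rows.
#'
#' @param df Table to write.
#' @param path Output path.
#' @param config Named list echoed into the comment header.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(config))
    writeLines(sprintf("# %s: %s", k, paste(config[[k]], collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path Table path.
#' @return `data.frame`; the parsed comment header is attached as
#'   attribute `"config"`.
#' @export
read_result_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          header = TRUE, stringsAsFactors = FALSE)
  cfg <- list()
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    k <- sub(":.*$", "", kv)
    cfg[[k]] <- trimws(sub("^[^:]*: ?", "", kv))
  }
  attr(df, "config") <- cfg
  df
}
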