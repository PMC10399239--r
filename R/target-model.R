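#' Construct a target region
#'
#' A target region is an independent mini-contig holding the analyzed span of
#' one gene: by default 2 kb of promoter followed by 1 kb of gene body, with
#' the transcriptional start site (TSS) as the first base of the body span.
#' Coordinates are 0-based and half-open throughout, so the promoter is
#' `[0, tss_offset)` and the body `[tss_offset, L)`.
#'
#' @param gene_id Gene identifier (opaque string).
#' @param sequence Forward-strand DNA sequence over `A`, `C`, `G`, `T`, `N`.
#' @param tss_offset 0-based offset of the TSS within the region; must lie
#'   strictly inside `(0, L)`. Default 2000 for the 2 kb + 1 kb geometry.
#' @return An object of class `target_region`: a list with `gene_id`,
#'   `sequence`, `length`, `tss_offset`.
#' @examples
#' r <- target_region("g1", "ACGTACGT", tss_offset = 4)
#' enumerate_sites(r)
#' @export
target_region <- function(gene_id, sequence, tss_offset = 2000L) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  sequence <- toupper(as.character(sequence))
  L <- nchar(sequence)
  .check_bases(sequence, gene_id)
  tss_offset <- as.integer(tss_offset)
  if (is.na(tss_offset) || tss_offset <= 0L || tss_offset >= L)
    stop(sprintf("gene %s: tss_offset must lie strictly inside (0, %d), got %s",
                 gene_id, L, tss_offset))
  structure(
    list(gene_id = gene_id, sequence = sequence, length = L,
         tss_offset = tss_offset),
    class = "target_region"
  )
}

#' @export
print.target_region <- function(x, ...) {
  cat(sprintf("<target_region> %s: %d nt, promoter [0,%d), body [%d,%d)\n",
              x$gene_id, x$length, x$tss_offset, x$tss_offset, x$length))
  invisible(x)
}

.check_bases <- function(sequence, gene_id) {
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L)
    stop(sprintf("gene %s: invalid base '%s' at offset %d (allowed: A,C,G,T,N)",
                 gene_id, substr(sequence, bad, bad), bad - 1L))
  invisible(TRUE)
}

#' Read target regions from FASTA plus a region table
#'
#' The FASTA record IDs are the gene IDs; the region table is tab-separated
#' with a header line and columns `gene_id`, `length`, `tss_offset`. Every
#' gene in the table must be present in the FASTA with the stated length.
#'
#' @param fasta_path Path to the FASTA file of region sequences.
#' @param region_table_path Path to the tab-separated region table.
#' @return Named list of [target_region] objects, in region-table order.
#' @export
read_target_regions <- function(fasta_path, region_table_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  tab <- utils::read.delim(region_table_path, header = TRUE,
                           colClasses = c("character", "integer", "integer"),
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "length", "tss_offset")
  if (!all(need %in% names(tab)))
    stop("region table must have header columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id in region table: ",
         tab$gene_id[duplicated(tab$gene_id)][1L])
  missing <- setdiff(tab$gene_id, ids)
  if (length(missing))
    stop("region table genes absent from FASTA: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  out <- vector("list", nrow(tab))
  names(out) <- tab$gene_id
  for (i in seq_len(nrow(tab))) {
    s <- as.character(seqs[[match(tab$gene_id[i], ids)]])
    if (nchar(s) != tab$length[i])
      stop(sprintf("gene %s: FASTA length %d does not match region table length %d",
                   tab$gene_id[i], nchar(s), tab$length[i]))
    out[[i]] <- target_region(tab$gene_id[i], s, tab$tss_offset[i])
  }
  out
}

# Context from the two downstream bases on the site's own strand. The full
# 2-nt window must be inside the region and N-free; otherwise "ambiguous"
# (targets are extracted subsequences, so flanking genome is unknown, and N
# voids any context it participates in -- matching bisulfite-caller practice).
.context_from_downstream <- function(b1, b2) {
  ctx <- rep("ambiguous", length(b1))
  ok <- !is.na(b1) & !is.na(b2) & b1 != "N" & b2 != "N"
  ctx[ok & b1 == "G"] <- "CpG"
  ctx[ok & b1 != "G" & b2 == "G"] <- "CHG"
  ctx[ok & b1 != "G" & b2 != "G"] <- "CHH"
  ctx
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# 1-based lookup returning NA outside [1, length(chars)]
.base_at <- function(chars, idx) {
  out <- rep(NA_character_, length(idx))
  ok <- idx >= 1L & idx <= length(chars)
  out[ok] <- chars[idx[ok]]
  out
}

#' Enumerate strand-resolved cytosine sites in a region
#'
#' Every forward-strand `C` becomes a `+` site and every forward-strand `G`
#' a `-` site (a cytosine on the reverse complement); positions always refer
#' to the forward-strand 0-based coordinate. Context is read from the two
#' bases downstream on the site's own strand: `CG*` is CpG, `CHG` is CHG and
#' `CHH` is CHH with H in `{A,C,T}`. Sites whose downstream 2-nt window runs
#' off the region end or contains `N` are labeled `ambiguous`; downstream
#' statistics exclude them. The region label is `promoter` iff
#' `position < tss_offset`.
#'
#' @param region A [target_region].
#' @return `data.frame` with columns `gene_id`, `position` (0-based),
#'   `strand` (`+`/`-`), `context` (`CpG`, `CHG`, `CHH`, `ambiguous`) and
#'   `region_label` (`promoter`/`body`), sorted by position then strand.
#' @export
enumerate_sites <- function(region) {
  stopifnot(inherits(region, "target_region"))
  chars <- strsplit(region$sequence, "", fixed = TRUE)[[1L]]
  L <- region$length

  pos_plus <- which(chars == "C") - 1L            # 0-based
  ctx_plus <- .context_from_downstream(.base_at(chars, pos_plus + 2L),
                                       .base_at(chars, pos_plus + 3L))

  pos_minus <- which(chars == "G") - 1L
  b1m <- unname(.COMPLEMENT[.base_at(chars, pos_minus)])      # fwd pos p-1
  b2m <- unname(.COMPLEMENT[.base_at(chars, pos_minus - 1L)]) # fwd pos p-2
  ctx_minus <- .context_from_downstream(b1m, b2m)

  out <- data.frame(
    gene_id = rep(region$gene_id, length(pos_plus) + length(pos_minus)),
    position = c(pos_plus, pos_minus),
    strand = rep(c("+", "-"), c(length(pos_plus), length(pos_minus))),
    context = c(ctx_plus, ctx_minus),
    stringsAsFactors = FALSE
  )
  out$region_label <- ifelse(out$position < region$tss_offset, "promoter", "body")
  out <- out[order(out$position, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate sites for a list of regions
#'
#' @param regions Named list of [target_region] objects.
#' @return Row-bound site `data.frame` (see [enumerate_sites()]).
#' @export
enumerate_sites_all <- function(regions) {
  do.call(rbind, lapply(regions, enumerate_sites))
}

#' Count context sites per 50-bp window
#'
#' Tallies unambiguous cytosine sites (both strands pooled, irrespective of
#' methylation status) in each half-open window `[k*w, (k+1)*w)`, giving the
#' context-abundance profile along a region.
#'
#' @param region A [target_region].
#' @param window_size Window width in nt; must divide the region length
#'   exactly (default 50, giving 60 windows for a 3 kb region).
#' @return `data.frame` with `window_index` (0-based), `context`, `n_sites`,
#'   one row per window x context (CpG, CHG, CHH), zero-filled.
#' @export
count_context_sites <- function(region, window_size = 50L) {
  window_size <- as.integer(window_size)
  if (region$length %% window_size != 0L)
    stop(sprintf("window_size %d does not divide region length %d",
                 window_size, region$length))
  n_win <- region$length %/% window_size
  sites <- enumerate_sites(region)
  sites <- sites[sites$context != "ambiguous", , drop = FALSE]
  win <- sites$position %/% window_size
  contexts <- c("CpG", "CHG", "CHH")
  counts <- table(factor(win, levels = 0:(n_win - 1L)),
                  factor(sites$context, levels = contexts))
  data.frame(
    gene_id = region$gene_id,
    window_index = rep(0:(n_win - 1L), times = length(contexts)),
    context = rep(contexts, each = n_win),
    n_sites = as.integer(counts),
    stringsAsFactors = FALSE
  )
}
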