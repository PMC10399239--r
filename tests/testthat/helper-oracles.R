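# Independent oracles used across the suite. These deliberately share no code
# with the package internals: site enumeration is re-done with perl-regex
# lookahead scans of both strands, and the Fisher p-value with a direct
# binomial-coefficient enumeration over all tables with the observed margins.

oracle_scan_strand <- function(seq) {
  pats <- c(CpG = "C(?=G[ACGT])", CHG = "C(?=[ACT]G)", CHH = "C(?=[ACT][ACT])")
  out <- list()
  for (cx in names(pats)) {
    m <- gregexpr(pats[[cx]], seq, perl = TRUE)[[1L]]
    if (m[1L] != -1L)
      out[[cx]] <- data.frame(pos0 = as.integer(m) - 1L, context = cx,
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

oracle_sites <- function(sequence) {
  L <- nchar(sequence)
  fwd <- oracle_scan_strand(sequence)
  rc <- chartr("ACGTN", "TGCAN",
               paste(rev(strsplit(sequence, "")[[1L]]), collapse = ""))
  rev <- oracle_scan_strand(rc)
  rows <- list()
  if (!is.null(fwd))
    rows$fwd <- data.frame(position = fwd$pos0, strand = "+",
                           context = fwd$context, stringsAsFactors = FALSE)
  if (!is.null(rev))
    rows$rev <- data.frame(position = L - 1L - rev$pos0, strand = "-",
                           context = rev$context, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(position = integer(), strand = character(),
                      context = character(), stringsAsFactors = FALSE))
  out <- out[order(out$position, match(out$strand, c("+", "-"))), ]
  rownames(out) <- NULL
  out
}

# Two-sided Fisher p by explicit enumeration with binomial coefficients.
oracle_fisher <- function(a, b, c, d, rel_tol = 1e-7) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  N <- r1 + r2
  x <- max(0, c1 - r2):min(r1, c1)
  pr <- exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(N, c1))
  p0 <- exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(N, c1))
  min(1, sum(pr[pr <= p0 * (1 + rel_tol)]))
}

random_sequence <- function(L, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Hand-built annotated count table for summary-stat tests.
make_annotated <- function(meth, unmeth, context = "CpG", region = "promoter",
                           gene = "g1", position = seq_along(meth) * 3L,
                           strand = "+") {
  data.frame(gene_id = gene, position = position,
             strand = rep_len(strand, length(meth)),
             meth_reads = as.integer(meth), unmeth_reads = as.integer(unmeth),
             context = rep_len(context, length(meth)),
             region_label = rep_len(region, length(meth)),
             stringsAsFactors = FALSE)
}
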