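# Independent brute-force re-implementations used as oracles. These are
# deliberately naive (per-record loops, no shared code with the package
# internals) so agreement is meaningful.

# Naive per-read pattern assembly: first-seen call per (read, site) wins.
brute_force_patterns <- function(calls, sites, chrom = "chr1") {
  seen <- list()          # key "read\rpos" -> methylated
  read_order <- character(0)
  conflicts <- 0L
  for (i in seq_len(nrow(calls))) {
    if (calls$context[i] != "CpG") next
    if (calls$chrom[i] != chrom) next
    if (!(calls$pos[i] %in% sites)) next
    key <- paste(calls$read_id[i], calls$pos[i], sep = "\r")
    if (!is.null(seen[[key]])) {
      if (seen[[key]] != calls$methylated[i]) conflicts <- conflicts + 1L
      next
    }
    seen[[key]] <- calls$methylated[i]
    if (!(calls$read_id[i] %in% read_order)) {
      read_order <- c(read_order, calls$read_id[i])
    }
  }
  patterns <- vapply(read_order, function(r) {
    chars <- vapply(sites, function(s) {
      v <- seen[[paste(r, s, sep = "\r")]]
      if (is.null(v)) "-" else if (v) "1" else "0"
    }, character(1))
    paste(chars, collapse = "")
  }, character(1))
  list(read_id = read_order, pattern = unname(patterns), conflicts = conflicts)
}

# Naive pattern counting with coverage filter, rank and lexicographic
# tie-break, plus per-site fractions over covering reads.
brute_force_count <- function(patterns, n_sites, min_cov = 1) {
  kept <- character(0)
  dropped <- 0L
  for (p in patterns) {
    chars <- strsplit(p, "", fixed = TRUE)[[1]]
    cov <- if (n_sites > 0) sum(chars != "-") / n_sites else 1
    if (cov >= min_cov) kept <- c(kept, p) else dropped <- dropped + 1L
  }
  u <- sort(unique(kept))
  counts <- vapply(u, function(x) sum(kept == x), integer(1))
  ord <- order(-counts, u)
  u <- u[ord]; counts <- unname(counts[ord])
  smf <- rep(NA_real_, n_sites)
  if (n_sites > 0 && length(kept)) {
    for (j in seq_len(n_sites)) {
      ch <- substr(kept, j, j)
      covering <- ch != "-"
      smf[j] <- if (any(covering)) mean(ch[covering] == "1") else NA_real_
    }
  }
  list(pattern = u, count = counts, dropped = dropped,
       total = length(kept), site_meth_fraction = smf)
}

# Random small fixture: reads x sites with per-cell missingness, returned as
# shuffled call records.
random_call_fixture <- function(seed, max_reads = 50L, max_sites = 8L) {
  set.seed(seed)
  n_reads <- sample.int(max_reads, 1L)
  n_sites <- sample.int(max_sites, 1L)
  sites <- sort(sample.int(500L, n_sites)) + 99L
  rows <- list()
  for (r in seq_len(n_reads)) {
    covered <- runif(n_sites) > 0.3
    if (!any(covered)) covered[sample.int(n_sites, 1L)] <- TRUE
    for (j in which(covered)) {
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sprintf("r%03d", r), chrom = "chr1", pos = sites[j],
        context = "CpG", methylated = runif(1) < 0.5, strand = "forward",
        stringsAsFactors = FALSE
      )
    }
  }
  calls <- do.call(rbind, rows)
  calls <- calls[sample.int(nrow(calls)), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, sites = sites, n_sites = n_sites)
}
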