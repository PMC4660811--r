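# Per-read epiallele assembly and counting: the computational core.
#
# The conventional per-site methylation fraction averages over molecules and
# masks allelic structure; the epiallele summary instead keeps the ordered
# methylation states of each sequenced molecule ('1' methylated,
# '0' unmethylated, '-' site not covered by the read) and counts the distinct
# strings.

#' Discover the CpG site index of an amplicon
#'
#' CpG site discovery is empirical: the site set is the union of normalized
#' CpG call positions observed inside the amplicon's primer-trimmed interval
#' (no reference FASTA is consulted). An empty site set is legal and expected
#' for a no-CpG control amplicon.
#'
#' @param calls A calls `data.frame` (normalized; see [read_bismark_calls()]).
#' @param amplicon A single-row `amplicon_config`.
#' @return An object of class `site_index`: a list with `amplicon_name`,
#'   `chrom`, `start`, `end`, `trim_start`, `trim_end` and `sites` (strictly
#'   increasing 0-based positions). The number of CpG calls on this
#'   chromosome falling outside the trimmed interval is tallied in the
#'   `n_outside` attribute.
#' @export
build_site_index <- function(calls, amplicon) {
  stopifnot(inherits(amplicon, "amplicon_config"), nrow(amplicon) == 1L)
  ti <- trimmed_interval(amplicon)
  cpg <- calls[calls$context == "CpG" & calls$chrom == amplicon$chrom, , drop = FALSE]
  inside <- cpg$pos >= ti$trim_start & cpg$pos < ti$trim_end
  idx <- structure(
    list(
      amplicon_name = amplicon$name,
      chrom = amplicon$chrom,
      start = amplicon$start,
      end = amplicon$end,
      trim_start = ti$trim_start,
      trim_end = ti$trim_end,
      sites = sort(unique(cpg$pos[inside]))
    ),
    class = "site_index"
  )
  attr(idx, "n_outside") <- sum(!inside)
  idx
}

#' Assemble per-read methylation pattern strings
#'
#' For every read with at least one CpG call on the index sites, builds the
#' ordered state string over the amplicon's sites: `'1'` methylated, `'0'`
#' unmethylated, `'-'` site not covered by the read. Duplicate calls for one
#' (read, site) — e.g. overlapping paired-end mates — are resolved
#' first-seen-wins; discarded duplicates that disagree with the kept call are
#' counted in the `conflicts` attribute.
#'
#' @param calls A calls `data.frame`.
#' @param index A `site_index` built from the same call universe.
#' @return A `data.frame` with columns `read_id`, `amplicon_name`, `pattern`,
#'   one row per read in order of first appearance; attribute `conflicts`.
#' @export
assemble_patterns <- function(calls, index) {
  stopifnot(inherits(index, "site_index"))
  sites <- index$sites
  empty <- data.frame(read_id = character(0), amplicon_name = character(0),
                      pattern = character(0), stringsAsFactors = FALSE)
  attr(empty, "conflicts") <- 0L
  if (!length(sites)) return(empty)
  on_site <- calls$context == "CpG" & calls$chrom == index$chrom &
    calls$pos %in% sites
  if (!any(on_site)) return(empty)
  dt <- data.table::data.table(
    read_id = calls$read_id[on_site],
    pos = calls$pos[on_site],
    methylated = calls$methylated[on_site]
  )
  dup <- duplicated(dt, by = c("read_id", "pos"))
  conflicts <- 0L
  if (any(dup)) {
    first <- dt[!dup]
    data.table::setkeyv(first, c("read_id", "pos"))
    dropped <- dt[dup]
    kept_state <- first[dropped, on = c("read_id", "pos")]$methylated
    conflicts <- sum(dropped$methylated != kept_state)
    dt <- dt[!dup]
  }
  reads <- unique(dt$read_id)
  i <- match(dt$read_id, reads)
  j <- match(dt$pos, sites)
  m <- matrix("-", nrow = length(reads), ncol = length(sites))
  m[cbind(i, j)] <- ifelse(dt$methylated, "1", "0")
  pattern <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  out <- data.frame(
    read_id = reads,
    amplicon_name = rep.int(index$amplicon_name, length(reads)),
    pattern = pattern,
    stringsAsFactors = FALSE
  )
  attr(out, "conflicts") <- conflicts
  out
}

#' Count and rank distinct methylation patterns
#'
#' Aggregates identical pattern strings into rows of (pattern, read count,
#' fraction of kept reads), ranked by count descending with lexicographic
#' tie-break on the pattern string so output order is deterministic. Reads
#' covering fewer than `min_coverage_fraction` of the amplicon's sites are
#' dropped before counting (the default 1.0 keeps only full-length
#' epialleles); the dropped count is reported. The per-site methylation
#' fraction is computed over covering reads only (`'-'` observations are
#' excluded from the denominator).
#'
#' @param patterns A patterns `data.frame` from [assemble_patterns()] (all
#'   rows must share one amplicon).
#' @param index The `site_index` the patterns were assembled against.
#' @param min_coverage_fraction Minimum fraction of sites a read must cover
#'   to be counted, in `[0, 1]`.
#' @param sample_name Sample identifier recorded in the summary.
#' @return An object of class `pattern_summary`: a list with
#'   `amplicon_name`, `sample_name`, `chrom`, `start`, `end`, `sites`,
#'   `rows` (data.frame `pattern`, `count`, `fraction`), `total_reads`,
#'   `dropped`, `site_meth_fraction`, `conflicts`.
#' @examples
#' # Three reads over two sites: rows rank "11" (2 reads) above "10" (1 read)
#' @export
count_patterns <- function(patterns, index, min_coverage_fraction = 1,
                           sample_name = "sample") {
  stopifnot(inherits(index, "site_index"),
            is.numeric(min_coverage_fraction),
            min_coverage_fraction >= 0, min_coverage_fraction <= 1)
  if (nrow(patterns) &&
      !all(patterns$amplicon_name == index$amplicon_name)) {
    stop("patterns span more than one amplicon", call. = FALSE)
  }
  n_sites <- length(index$sites)
  pat <- patterns$pattern
  if (n_sites > 0L && length(pat)) {
    covered <- 1 - (nchar(gsub("[^-]", "", pat)) / n_sites)
    keep <- covered >= min_coverage_fraction
  } else {
    keep <- rep.int(TRUE, length(pat))
  }
  kept <- pat[keep]
  dropped <- sum(!keep)
  if (length(kept)) {
    tab <- table(kept)
    rows <- data.frame(
      pattern = names(tab),
      count = as.integer(tab),
      stringsAsFactors = FALSE
    )
    rows <- rows[order(-rows$count, rows$pattern), , drop = FALSE]
    rownames(rows) <- NULL
    rows$fraction <- rows$count / sum(rows$count)
  } else {
    rows <- data.frame(pattern = character(0), count = integer(0),
                       fraction = numeric(0), stringsAsFactors = FALSE)
  }
  site_meth_fraction <- site_fractions(rows, n_sites)
  structure(
    list(
      amplicon_name = index$amplicon_name,
      sample_name = sample_name,
      chrom = index$chrom,
      start = index$start,
      end = index$end,
      sites = index$sites,
      rows = rows,
      total_reads = sum(rows$count),
      dropped = dropped,
      site_meth_fraction = site_meth_fraction,
      conflicts = attr(patterns, "conflicts") %||% 0L
    ),
    class = "pattern_summary"
  )
}

# Per-site methylated fraction among covering reads, from aggregated
# (pattern, count) rows; NA at sites no kept read covers.
site_fractions <- function(rows, n_sites) {
  if (n_sites == 0L) return(numeric(0))
  if (!nrow(rows)) return(rep.int(NA_real_, n_sites))
  chars <- matrix(unlist(strsplit(rows$pattern, "", fixed = TRUE), use.names = FALSE),
                  nrow = nrow(rows), byrow = TRUE)
  meth <- colSums((chars == "1") * rows$count)
  cov <- colSums((chars != "-") * rows$count)
  frac <- ifelse(cov > 0, meth / cov, NA_real_)
  as.numeric(frac)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bisulfite conversion QC from non-CpG calls
#'
#' Cytosines outside CpG context are essentially unmethylated in human DNA,
#' so the fraction of non-CpG calls read as unmethylated estimates the
#' bisulfite conversion efficiency; values near 1 indicate complete
#' conversion. Unknown-context calls are excluded.
#'
#' @param calls A calls `data.frame`.
#' @param sample_name Sample identifier.
#' @param conflicts Duplicate-call conflict count to carry into the report.
#' @return An object of class `qc_report`: `sample_name`, `conversion_rate`
#'   (`NA` and `conversion_defined = FALSE` when there are no non-CpG
#'   calls), `context_counts` (per-context methylated/unmethylated tallies),
#'   `malformed_records`, `call_conflicts`.
#' @export
compute_qc <- function(calls, sample_name = "sample", conflicts = 0L) {
  noncpg <- calls$context %in% c("CHG", "CHH")
  n <- sum(noncpg)
  rate <- if (n > 0L) sum(!calls$methylated[noncpg]) / n else NA_real_
  counts <- data.frame(
    context = c("CHG", "CHH"),
    methylated = c(sum(calls$context == "CHG" & calls$methylated),
                   sum(calls$context == "CHH" & calls$methylated)),
    unmethylated = c(sum(calls$context == "CHG" & !calls$methylated),
                     sum(calls$context == "CHH" & !calls$methylated)),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      sample_name = sample_name,
      conversion_rate = rate,
      conversion_defined = n > 0L,
      n_noncpg = n,
      context_counts = counts,
      malformed_records = attr(calls, "malformed") %||% 0L,
      call_conflicts = as.integer(conflicts)
    ),
    class = "qc_report"
  )
}

#' @export
print.pattern_summary <- function(x, max_rows = 10L, ...) {
  cat(sprintf("Methylation pattern summary: %s (sample %s)\n",
              x$amplicon_name, x$sample_name))
  cat(sprintf("  %s:%d-%d, %d CpG site(s)\n", x$chrom, x$start, x$end,
              length(x$sites)))
  if (!length(x$sites)) {
    cat("  no CpG sites observed (control-like amplicon)\n")
  }
  cat(sprintf("  %d read(s) kept, %d dropped by coverage filter\n",
              x$total_reads, x$dropped))
  if (nrow(x$rows)) {
    shown <- utils::head(x$rows, max_rows)
    cat(sprintf("  %-20s %8s %9s\n", "pattern", "count", "fraction"))
    for (i in seq_len(nrow(shown))) {
      cat(sprintf("  %-20s %8d %9.4f\n", shown$pattern[i], shown$count[i],
                  shown$fraction[i]))
    }
    if (nrow(x$rows) > max_rows) {
      cat(sprintf("  ... and %d more pattern(s)\n", nrow(x$rows) - max_rows))
    }
  }
  invisible(x)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Bisulfite conversion QC: sample %s\n", x$sample_name))
  if (x$conversion_defined) {
    cat(sprintf("  conversion rate: %.4f (%d non-CpG calls)\n",
                x$conversion_rate, x$n_noncpg))
  } else {
    cat("  conversion rate: undefined (no non-CpG calls)\n")
  }
  cat(sprintf("  malformed records: %d; call conflicts: %d\n",
              x$malformed_records, x$call_conflicts))
  invisible(x)
}
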