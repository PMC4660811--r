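# Output writers: the per-sample tab-delimited pattern summary and the
# self-contained HTML visualization, plus the readers used for round-trip
# verification.

TSV_FORMAT_VERSION <- "1"

#' Write the per-sample pattern summary TSV
#'
#' One row per (amplicon, pattern), grouped by amplicon in configuration
#' order with patterns in rank order within each group. `#`-prefixed metadata
#' lines record the tool version, the TSV format version and any parameters
#' supplied. Output is UTF-8 with LF line endings and is byte-identical
#' across repeated runs on identical input.
#'
#' Columns: `sample`, `amplicon`, `chrom`, `start`, `end`, `n_sites`,
#' `site_positions` (semicolon-joined, 0-based), `pattern`, `raw_count`,
#' `fraction` (6 decimals). Coordinates are the internal 0-based half-open
#' convention.
#'
#' @param summaries A list of `pattern_summary` objects (one sample).
#' @param path Output file path.
#' @param params Named list of run parameters echoed into metadata lines.
#' @return `path`, invisibly.
#' @export
write_pattern_tsv <- function(summaries, path, params = list()) {
  meta <- c(
    sprintf("# amplimeth %s", pkg_version()),
    sprintf("# tsv_format_version=%s", TSV_FORMAT_VERSION)
  )
  if (length(params)) {
    meta <- c(meta, sprintf("# %s=%s", names(params),
                            vapply(params, format_param, character(1))))
  }
  header <- paste(c("sample", "amplicon", "chrom", "start", "end", "n_sites",
                    "site_positions", "pattern", "raw_count", "fraction"),
                  collapse = "\t")
  rows <- character(0)
  for (s in summaries) {
    stopifnot(inherits(s, "pattern_summary"))
    if (!nrow(s$rows)) next
    rows <- c(rows, sprintf(
      "%s\t%s\t%s\t%d\t%d\t%d\t%s\t%s\t%d\t%.6f",
      s$sample_name, s$amplicon_name, s$chrom, s$start, s$end,
      length(s$sites), paste(s$sites, collapse = ";"),
      s$rows$pattern, s$rows$count, s$rows$fraction
    ))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(meta, header, rows), con)
  invisible(path)
}

format_param <- function(x) paste(format(x, trim = TRUE), collapse = ",")

pkg_version <- function() {
  as.character(utils::packageVersion("amplimeth"))
}

#' Read a pattern summary TSV back into `pattern_summary` objects
#'
#' Inverse of [write_pattern_tsv()] for the fields the TSV carries: amplicon
#' metadata, site positions, and the ranked (pattern, count, fraction) rows.
#' Per-site methylation fractions are recomputed from the aggregated rows
#' (which is exact, since they are weighted column tallies of the rows).
#' Amplicons that contributed no rows are not recoverable from the file.
#'
#' @param path Path to a TSV written by [write_pattern_tsv()].
#' @return A list of `pattern_summary` objects in file order.
#' @export
read_pattern_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  if (!length(lines)) stop("pattern TSV has no header line", call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  if (!length(body)) return(list())
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != length(header))) {
    stop("malformed pattern TSV data line", call. = FALSE)
  }
  m <- matrix(unlist(parts, use.names = FALSE), ncol = length(header), byrow = TRUE)
  colnames(m) <- header
  out <- list()
  for (amp in unique(m[, "amplicon"])) {
    g <- m[m[, "amplicon"] == amp, , drop = FALSE]
    sites <- if (g[1L, "site_positions"] == "") integer(0) else
      as.integer(strsplit(g[1L, "site_positions"], ";", fixed = TRUE)[[1L]])
    rows <- data.frame(
      pattern = g[, "pattern"],
      count = as.integer(g[, "raw_count"]),
      fraction = as.numeric(g[, "fraction"]),
      stringsAsFactors = FALSE
    )
    out[[amp]] <- structure(
      list(
        amplicon_name = amp,
        sample_name = g[1L, "sample"],
        chrom = g[1L, "chrom"],
        start = as.integer(g[1L, "start"]),
        end = as.integer(g[1L, "end"]),
        sites = sites,
        rows = rows,
        total_reads = sum(rows$count),
        dropped = NA_integer_,
        site_meth_fraction = site_fractions(rows, length(sites)),
        conflicts = NA_integer_
      ),
      class = "pattern_summary"
    )
  }
  unname(out)
}

#' Write the per-sample QC TSV
#'
#' @param qc A `qc_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qc_tsv <- function(qc, path) {
  stopifnot(inherits(qc, "qc_report"))
  lines <- c(
    sprintf("# amplimeth %s", pkg_version()),
    paste(c("sample", "conversion_rate", "n_noncpg",
            "chg_methylated", "chg_unmethylated",
            "chh_methylated", "chh_unmethylated",
            "malformed_records", "call_conflicts"), collapse = "\t"),
    sprintf("%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d",
            qc$sample_name,
            if (qc$conversion_defined) sprintf("%.6f", qc$conversion_rate) else "NA",
            qc$n_noncpg,
            qc$context_counts$methylated[qc$context_counts$context == "CHG"],
            qc$context_counts$unmethylated[qc$context_counts$context == "CHG"],
            qc$context_counts$methylated[qc$context_counts$context == "CHH"],
            qc$context_counts$unmethylated[qc$context_counts$context == "CHH"],
            qc$malformed_records, qc$call_conflicts)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# --- HTML -------------------------------------------------------------------

#' Render the self-contained HTML visualization
#'
#' Produces a single static HTML document with no external fetches: per
#' amplicon, a grid whose columns are the CpG sites in genomic order and
#' whose rows are the patterns in rank order, with methylated, unmethylated
#' and missing cells rendered distinctly, per-row read counts and
#' percentages, and a per-site methylation-fraction track. A QC panel shows
#' the bisulfite conversion rate. The complete summary data is embedded as a
#' machine-readable JSON data island (`<script type="application/json">`),
#' recoverable losslessly with [read_html_data()]. Amplicons with no
#' observed CpG sites are rendered with an explicit notice.
#'
#' @param summaries A list of `pattern_summary` objects.
#' @param qc A `qc_report`, or `NULL` to omit the QC panel.
#' @param path Output file path.
#' @param max_patterns Maximum pattern rows drawn per amplicon grid (the data
#'   island always contains all rows).
#' @return `path`, invisibly.
#' @export
render_html <- function(summaries, qc, path, max_patterns = 50L) {
  island <- summaries_to_json(summaries, qc)
  sample_name <- if (length(summaries)) summaries[[1L]]$sample_name
    else if (!is.null(qc)) qc$sample_name else "sample"
  head_html <- c(
    "<!DOCTYPE html>",
    "<html lang=\"en\">",
    "<head>",
    "<meta charset=\"utf-8\"/>",
    sprintf("<title>Methylation patterns: %s</title>", html_escape(sample_name)),
    "<style>",
    "body{font-family:Helvetica,Arial,sans-serif;margin:2em;color:#222;}",
    "h1{font-size:1.4em;} h2{font-size:1.1em;margin-top:2em;}",
    "table.grid{border-collapse:collapse;margin:0.5em 0;}",
    "table.grid td,table.grid th{padding:2px 4px;font-size:0.8em;text-align:center;}",
    "td.cell{width:16px;height:16px;border-radius:8px;border:1px solid #555;}",
    "td.meth{background:#1a1a1a;}",
    "td.unmeth{background:#ffffff;}",
    "td.missing{background:#cccccc;border-style:dashed;}",
    "td.count,td.pct{text-align:right;padding-left:10px;}",
    "tr.sitetrack td{font-size:0.7em;color:#444;}",
    ".qc{border:1px solid #999;padding:0.8em;margin:1em 0;background:#f7f7f7;}",
    ".no-cpg-notice{color:#8a4500;font-style:italic;}",
    ".legend span{margin-right:1.2em;}",
    "</style>",
    "</head>",
    "<body>",
    sprintf("<h1>DNA methylation patterns &mdash; sample %s</h1>",
            html_escape(sample_name)),
    paste0("<p class=\"legend\"><span>&#9679; methylated</span>",
           "<span>&#9675; unmethylated</span>",
           "<span>&#9634; not covered</span></p>")
  )
  qc_html <- if (!is.null(qc)) render_qc_panel(qc) else character(0)
  body_html <- unlist(lapply(summaries, render_amplicon_section,
                             max_patterns = max_patterns))
  tail_html <- c(
    sprintf("<script type=\"application/json\" id=\"amplimeth-data\">%s</script>",
            island),
    "</body>",
    "</html>"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(head_html, qc_html, body_html, tail_html), con)
  invisible(path)
}

render_qc_panel <- function(qc) {
  conv <- if (qc$conversion_defined) {
    sprintf("%.4f%%", 100 * qc$conversion_rate)
  } else {
    "undefined (no non-CpG calls)"
  }
  c("<div class=\"qc\">",
    "<strong>Bisulfite conversion QC</strong><br/>",
    sprintf("Conversion rate (unmethylated / total non-CpG calls): %s<br/>", conv),
    sprintf("Non-CpG calls: %d; malformed records: %d; call conflicts: %d",
            qc$n_noncpg, qc$malformed_records, qc$call_conflicts),
    "</div>")
}

render_amplicon_section <- function(s, max_patterns = 50L) {
  title <- sprintf("<h2>%s (%s:%d-%d)</h2>", html_escape(s$amplicon_name),
                   html_escape(s$chrom), s$start, s$end)
  if (!length(s$sites)) {
    return(c(title,
             paste0("<p class=\"no-cpg-notice\">No CpG sites observed in this ",
                    "amplicon (control-like region: all cytosines converted).</p>")))
  }
  head_row <- paste0(
    "<tr><th></th>",
    paste0("<th>", s$sites, "</th>", collapse = ""),
    "<th>reads</th><th>%</th></tr>"
  )
  shown <- utils::head(s$rows, max_patterns)
  pat_rows <- vapply(seq_len(nrow(shown)), function(i) {
    chars <- strsplit(shown$pattern[i], "", fixed = TRUE)[[1L]]
    cls <- ifelse(chars == "1", "meth", ifelse(chars == "0", "unmeth", "missing"))
    cells <- paste0("<td class=\"cell ", cls, "\"></td>", collapse = "")
    sprintf("<tr><td>%d</td>%s<td class=\"count\">%d</td><td class=\"pct\">%.4f%%</td></tr>",
            i, cells, shown$count[i], 100 * shown$fraction[i])
  }, character(1))
  track <- paste0(
    "<tr class=\"sitetrack\"><td>site&nbsp;meth</td>",
    paste0("<td>", ifelse(is.na(s$site_meth_fraction), "&mdash;",
                          sprintf("%.0f%%", 100 * s$site_meth_fraction)),
           "</td>", collapse = ""),
    "<td></td><td></td></tr>"
  )
  more <- if (nrow(s$rows) > max_patterns) {
    sprintf("<p>... and %d more pattern(s); see embedded data.</p>",
            nrow(s$rows) - max_patterns)
  } else character(0)
  c(title,
    sprintf("<p>%d read(s) kept, %d dropped by coverage filter, %d CpG site(s).</p>",
            s$total_reads, s$dropped, length(s$sites)),
    "<table class=\"grid\">", head_row, pat_rows, track, "</table>", more)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

summaries_to_json <- function(summaries, qc) {
  payload <- list(
    format = "amplimeth-data-island",
    version = TSV_FORMAT_VERSION,
    summaries = lapply(summaries, function(s) {
      list(
        amplicon_name = s$amplicon_name,
        sample_name = s$sample_name,
        chrom = s$chrom,
        start = s$start,
        end = s$end,
        sites = as.integer(s$sites),
        rows = list(
          pattern = s$rows$pattern,
          count = s$rows$count,
          fraction = s$rows$fraction
        ),
        total_reads = s$total_reads,
        dropped = s$dropped,
        site_meth_fraction = s$site_meth_fraction,
        conflicts = s$conflicts
      )
    }),
    qc = if (is.null(qc)) NULL else unclass(qc)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null")
  # keep the island safe inside <script>
  gsub("</", "<\\/", json, fixed = TRUE)
}

#' Extract the embedded data island from a rendered HTML file
#'
#' Recovers the `pattern_summary` list (and QC report, if present) embedded
#' by [render_html()]. This is the lossless machine-readable path back out
#' of the visualization.
#'
#' @param path Path to an HTML file written by [render_html()].
#' @return A list with elements `summaries` (list of `pattern_summary`) and
#'   `qc` (a `qc_report` or `NULL`).
#' @export
read_html_data <- function(path) {
  html <- paste(readLines(path, warn = FALSE), collapse = "\n")
  m <- regmatches(html, regexpr(
    "<script type=\"application/json\" id=\"amplimeth-data\">.*?</script>", html))
  if (!length(m)) stop("no data island found in ", path, call. = FALSE)
  json <- sub("^<script[^>]*>", "", sub("</script>$", "", m))
  json <- gsub("<\\/", "</", json, fixed = TRUE)
  payload <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  summaries <- lapply(payload$summaries, function(s) {
    rows <- data.frame(
      pattern = as.character(unlist(s$rows$pattern)),
      count = as.integer(unlist(s$rows$count)),
      fraction = as.numeric(unlist(s$rows$fraction)),
      stringsAsFactors = FALSE
    )
    if (!length(s$rows$pattern)) {
      rows <- data.frame(pattern = character(0), count = integer(0),
                         fraction = numeric(0), stringsAsFactors = FALSE)
    }
    structure(
      list(
        amplicon_name = s$amplicon_name,
        sample_name = s$sample_name,
        chrom = s$chrom,
        start = as.integer(s$start),
        end = as.integer(s$end),
        sites = as.integer(unlist(s$sites)),
        rows = rows,
        total_reads = as.integer(s$total_reads),
        dropped = as.integer(s$dropped),
        site_meth_fraction = as.numeric(
          vapply(s$site_meth_fraction, function(v) if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
        ),
        conflicts = as.integer(s$conflicts)
      ),
      class = "pattern_summary"
    )
  })
  qc <- NULL
  if (!is.null(payload$qc)) {
    q <- payload$qc
    cc <- q$context_counts  # serialized as an array of row objects
    qc <- structure(
      list(
        sample_name = q$sample_name,
        conversion_rate = if (is.null(q$conversion_rate)) NA_real_ else as.numeric(q$conversion_rate),
        conversion_defined = isTRUE(q$conversion_defined),
        n_noncpg = as.integer(q$n_noncpg),
        context_counts = data.frame(
          context = vapply(cc, function(r) as.character(r$context), character(1)),
          methylated = vapply(cc, function(r) as.integer(r$methylated), integer(1)),
          unmethylated = vapply(cc, function(r) as.integer(r$unmethylated), integer(1)),
          stringsAsFactors = FALSE
        ),
        malformed_records = as.integer(q$malformed_records),
        call_conflicts = as.integer(q$call_conflicts)
      ),
      class = "qc_report"
    )
  }
  list(summaries = summaries, qc = qc)
}
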