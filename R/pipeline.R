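#' Summarize one sample's methylation patterns over an amplicon panel
#'
#' The end-to-end pipeline for a single sample: read the extractor file(s),
#' discover each amplicon's CpG sites, assemble per-read pattern strings,
#' count and rank the distinct patterns, and compute conversion QC. When
#' `output_dir` is given, writes `<sample>.patterns.tsv`, `<sample>.html`
#' and `<sample>.qc.tsv`.
#'
#' @param amplicons An `amplicon_config`, or a path to a config file (read
#'   with `coordinate_style`).
#' @param extractor_paths One or more extractor file paths; calls are pooled.
#' @param sample_name Sample identifier used in outputs and file names.
#' @param output_dir Output directory, or `NULL` to skip writing files.
#' @param min_coverage_fraction Coverage filter passed to [count_patterns()].
#' @param coordinate_style Coordinate convention of a config file path
#'   (`"bed"` or `"ucsc"`); ignored when `amplicons` is already parsed.
#' @param strand_mode Strand handling passed to [read_bismark_calls()].
#' @param verbose Emit a per-amplicon summary line via [message()].
#' @return A list with `summaries` (list of `pattern_summary`, config
#'   order), `qc` (a `qc_report`) and, when files were written, `files`
#'   (named character vector of the three paths).
#' @examples
#' \donttest{
#' cfg <- read_amplicon_config(system.file("extdata",
#'   "amplicon_panel_hg38.tsv", package = "amplimeth"),
#'   coordinate_style = "ucsc")
#' }
#' @export
summarize_sample <- function(amplicons, extractor_paths, sample_name,
                             output_dir = NULL, min_coverage_fraction = 1,
                             coordinate_style = c("bed", "ucsc"),
                             strand_mode = c("auto", "forward", "reverse"),
                             verbose = TRUE) {
  coordinate_style <- match.arg(coordinate_style)
  strand_mode <- match.arg(strand_mode)
  if (is.character(amplicons)) {
    amplicons <- read_amplicon_config(amplicons, coordinate_style)
  }
  stopifnot(inherits(amplicons, "amplicon_config"))
  missing <- extractor_paths[!file.exists(extractor_paths)]
  if (length(missing)) {
    stop("extractor file not found: ", missing[1L], call. = FALSE)
  }
  call_sets <- lapply(extractor_paths, read_bismark_calls, strand = strand_mode)
  calls <- do.call(rbind, call_sets)
  attr(calls, "malformed") <- sum(vapply(call_sets, function(x)
    attr(x, "malformed") %||% 0L, integer(1)))

  summaries <- vector("list", nrow(amplicons))
  total_conflicts <- 0L
  for (k in seq_len(nrow(amplicons))) {
    amp <- amplicons[k, , drop = FALSE]
    class(amp) <- c("amplicon_config", "data.frame")
    index <- build_site_index(calls, amp)
    patterns <- assemble_patterns(calls, index)
    s <- count_patterns(patterns, index,
                        min_coverage_fraction = min_coverage_fraction,
                        sample_name = sample_name)
    total_conflicts <- total_conflicts + s$conflicts
    summaries[[k]] <- s
    if (verbose) {
      message(sprintf(
        "amplicon %s: %d read(s) seen, %d pattern(s) kept (%d reads), %d dropped",
        amp$name, nrow(patterns), nrow(s$rows), s$total_reads, s$dropped))
    }
  }
  qc <- compute_qc(calls, sample_name = sample_name,
                   conflicts = total_conflicts)
  out <- list(summaries = summaries, qc = qc)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    params <- list(
      sample = sample_name,
      min_coverage_fraction = min_coverage_fraction,
      coordinate_style = coordinate_style,
      strand_mode = strand_mode,
      extractor_files = paste(basename(extractor_paths), collapse = ",")
    )
    files <- c(
      patterns = file.path(output_dir, paste0(sample_name, ".patterns.tsv")),
      html = file.path(output_dir, paste0(sample_name, ".html")),
      qc = file.path(output_dir, paste0(sample_name, ".qc.tsv"))
    )
    write_pattern_tsv(summaries, files[["patterns"]], params = params)
    render_html(summaries, qc, files[["html"]])
    write_qc_tsv(qc, files[["qc"]])
    out$files <- files
  }
  out
}
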