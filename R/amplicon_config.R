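#' Read a BED-like amplicon definition file
#'
#' Parses the tab-separated amplicon configuration that defines the targeted
#' regions of a bisulfite PCR panel. Each non-comment line gives
#' `chrom`, `start`, `end`, `name`, and optionally the forward and reverse
#' primer lengths (genome-annealing bases). Primer-annealing ends of an
#' amplicon carry primer, not template, methylation signal, so the primer
#' lengths define the interval inside which CpG sites are scored (see
#' [trimmed_interval()]).
#'
#' Coordinates are normalized on input to the package-internal convention:
#' 0-based, half-open. `coordinate_style = "bed"` means the file already uses
#' that convention; `"ucsc"` means 1-based fully-closed spans as printed by
#' genome browsers (`chrN:s-e`), converted by `start - 1`.
#'
#' @param path Path to the configuration file. Lines starting with `#` are
#'   ignored.
#' @param coordinate_style Either `"bed"` (0-based half-open, the default) or
#'   `"ucsc"` (1-based fully-closed).
#' @return A `data.frame` of class `amplicon_config` with columns `name`,
#'   `chrom`, `start`, `end`, `fwd_primer_len`, `rev_primer_len`, in file
#'   order. Coordinates are 0-based half-open.
#' @examples
#' cfg_path <- system.file("extdata", "amplicon_panel_hg38.tsv",
#'                         package = "amplimeth")
#' cfg <- read_amplicon_config(cfg_path, coordinate_style = "ucsc")
#' nrow(cfg)
#' @export
read_amplicon_config <- function(path, coordinate_style = c("bed", "ucsc")) {
  coordinate_style <- match.arg(coordinate_style)
  if (!file.exists(path)) {
    stop("amplicon config file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(empty_amplicon_config())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4L)) {
    bad <- which(nf < 4L)[1L]
    stop(sprintf(
      "malformed amplicon config line %d: expected at least 4 tab-separated columns, got %d",
      line_no[bad], nf[bad]
    ), call. = FALSE)
  }
  grab <- function(i, default = NA_character_) {
    vapply(parts, function(p) if (length(p) >= i) p[[i]] else default, character(1))
  }
  chrom <- grab(1L)
  start <- suppressWarnings(as.integer(grab(2L)))
  end <- suppressWarnings(as.integer(grab(3L)))
  name <- grab(4L)
  fwd <- grab(5L)
  rev <- grab(6L)
  if (any(nf < 6L)) {
    warning("primer-length columns absent on ", sum(nf < 6L),
            " line(s); defaulting missing primer lengths to 0", call. = FALSE)
  }
  fwd <- suppressWarnings(as.integer(ifelse(is.na(fwd) | fwd == "", "0", fwd)))
  rev <- suppressWarnings(as.integer(ifelse(is.na(rev) | rev == "", "0", rev)))

  bad_num <- which(is.na(start) | is.na(end) | is.na(fwd) | is.na(rev))
  if (length(bad_num)) {
    stop(sprintf("malformed amplicon config line %d: non-integer coordinate or primer length",
                 line_no[bad_num[1L]]), call. = FALSE)
  }
  if (coordinate_style == "ucsc") {
    start <- start - 1L
  }
  bad_span <- which(start >= end)
  if (length(bad_span)) {
    stop(sprintf("invalid amplicon on config line %d ('%s'): start >= end",
                 line_no[bad_span[1L]], name[bad_span[1L]]), call. = FALSE)
  }
  if (anyDuplicated(name)) {
    dup <- name[duplicated(name)][1L]
    stop("duplicate amplicon name in config: '", dup, "'", call. = FALSE)
  }
  bad_chrom <- which(is.na(chrom) | chrom == "")
  if (length(bad_chrom)) {
    stop(sprintf("invalid amplicon on config line %d: empty chromosome",
                 line_no[bad_chrom[1L]]), call. = FALSE)
  }
  if (any(fwd < 0L) || any(rev < 0L)) {
    stop("negative primer length in amplicon config", call. = FALSE)
  }
  bad_trim <- which(fwd + rev >= end - start)
  if (length(bad_trim)) {
    stop(sprintf(
      "invalid amplicon '%s': primer lengths (%d + %d) leave no scorable interval in a %d bp amplicon",
      name[bad_trim[1L]], fwd[bad_trim[1L]], rev[bad_trim[1L]],
      end[bad_trim[1L]] - start[bad_trim[1L]]
    ), call. = FALSE)
  }
  cfg <- data.frame(
    name = name, chrom = chrom, start = start, end = end,
    fwd_primer_len = fwd, rev_primer_len = rev,
    stringsAsFactors = FALSE
  )
  class(cfg) <- c("amplicon_config", "data.frame")
  cfg
}

empty_amplicon_config <- function() {
  cfg <- data.frame(
    name = character(0), chrom = character(0),
    start = integer(0), end = integer(0),
    fwd_primer_len = integer(0), rev_primer_len = integer(0),
    stringsAsFactors = FALSE
  )
  class(cfg) <- c("amplicon_config", "data.frame")
  cfg
}

#' Write an amplicon configuration back to disk
#'
#' Serializes an `amplicon_config` in the same tab-separated layout accepted
#' by [read_amplicon_config()], so that write followed by read is the
#' identity.
#'
#' @param config An `amplicon_config`.
#' @param path Output file path.
#' @param coordinate_style Coordinate convention to write (`"bed"` or
#'   `"ucsc"`).
#' @return `path`, invisibly.
#' @export
write_amplicon_config <- function(config, path, coordinate_style = c("bed", "ucsc")) {
  coordinate_style <- match.arg(coordinate_style)
  stopifnot(inherits(config, "amplicon_config"))
  start <- config$start
  if (coordinate_style == "ucsc") start <- start + 1L
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
                   config$chrom, start, config$end, config$name,
                   config$fwd_primer_len, config$rev_primer_len)
  writeLines(lines, path)
  invisible(path)
}

#' Primer-trimmed scorable interval of each amplicon
#'
#' CpG positions that fall under the primer-annealing sequence reflect the
#' synthetic primer, not the template molecule, and must not be scored. The
#' trimmed interval is `[start + fwd_primer_len, end - rev_primer_len)` in
#' the internal 0-based half-open convention.
#'
#' @param config An `amplicon_config` (any number of rows).
#' @return A `data.frame` with columns `name`, `chrom`, `trim_start`,
#'   `trim_end` (0-based half-open).
#' @examples
#' cfg <- data.frame(name = "a", chrom = "chr1", start = 100L, end = 200L,
#'                   fwd_primer_len = 20L, rev_primer_len = 25L)
#' class(cfg) <- c("amplicon_config", "data.frame")
#' trimmed_interval(cfg)  # [120, 175)
#' @export
trimmed_interval <- function(config) {
  stopifnot(inherits(config, "amplicon_config"))
  data.frame(
    name = config$name,
    chrom = config$chrom,
    trim_start = config$start + config$fwd_primer_len,
    trim_end = config$end - config$rev_primer_len,
    stringsAsFactors = FALSE
  )
}

#' Read a sample manifest
#'
#' The manifest is tab-separated with a required header line naming the
#' columns `sample_name`, `description`, `accession`. `#`-prefixed comment
#' lines are ignored. Sample names must be unique.
#'
#' @param path Path to the manifest file.
#' @return A `data.frame` with columns `sample_name`, `description`,
#'   `accession`.
#' @examples
#' mf <- read_sample_manifest(system.file("extdata", "sample_manifest.tsv",
#'                                        package = "amplimeth"))
#' nrow(mf)
#' @export
read_sample_manifest <- function(path) {
  if (!file.exists(path)) {
    stop("sample manifest not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) {
    stop("sample manifest has no header line", call. = FALSE)
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  need <- c("sample_name", "description", "accession")
  if (!identical(header[seq_along(need)], need)) {
    stop("sample manifest header must be: ", paste(need, collapse = "\t"),
         call. = FALSE)
  }
  body <- lines[-1L]
  if (!length(body)) {
    return(data.frame(sample_name = character(0), description = character(0),
                      accession = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  grab <- function(i) vapply(parts, function(p) if (length(p) >= i) p[[i]] else "", character(1))
  mf <- data.frame(
    sample_name = grab(1L), description = grab(2L), accession = grab(3L),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(mf$sample_name)) {
    stop("duplicate sample_name in manifest: '",
         mf$sample_name[duplicated(mf$sample_name)][1L], "'", call. = FALSE)
  }
  if (any(mf$sample_name == "")) {
    stop("empty sample_name in manifest", call. = FALSE)
  }
  mf
}

#' @export
print.amplicon_config <- function(x, ...) {
  cat(sprintf("Amplicon configuration: %d amplicon(s)\n", nrow(x)))
  if (nrow(x)) {
    ti <- trimmed_interval(x)
    cat(sprintf("  scorable span total: %d bp\n",
                sum(ti$trim_end - ti$trim_start)))
  }
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  invisible(x)
}
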