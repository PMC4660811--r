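# Bismark methylation-extractor I/O.
#
# Extractor format, one call per line:
#   read_id <tab> state <tab> chrom <tab> pos(1-based) <tab> call letter
# state is '+' (methylated) or '-' (unmethylated); the call letter encodes the
# context and repeats the state in its case: Z/z CpG, X/x CHG, H/h CHH,
# U/u unknown. An optional leading "Bismark methylation extractor ..." header
# line is skipped.

CONTEXT_BY_LETTER <- c(z = "CpG", x = "CHG", h = "CHH", u = "unknown")

#' Read a Bismark methylation-extractor file
#'
#' Parses extractor output into one row per cytosine call, converting
#' positions to the internal 0-based convention and collapsing reverse-strand
#' CpG calls onto the forward-strand C (see [normalize_cpg_strand()]).
#' Plain-text and gzip input are auto-detected by magic bytes. Files are read
#' in fixed-size chunks so memory stays bounded regardless of file size.
#'
#' Strand handling: extractor output files carry their bisulfite strand in
#' the filename (`OT` original top, `OB` original bottom, also `CTOT`/`CTOB`).
#' With `strand = "auto"` the filename decides; when no token is present the
#' calls are used at their reported positions with a warning. `"forward"` and
#' `"reverse"` force the designation for the whole file.
#'
#' Records whose state symbol contradicts the call-letter case (e.g. `+`
#' with lowercase `z`), or that carry an unrecognized letter or position, are
#' skipped and counted in the `malformed` attribute. A line with the wrong
#' number of columns is a hard parse error naming the line.
#'
#' @param path Path to the extractor file (text or gzip).
#' @param strand One of `"auto"`, `"forward"`, `"reverse"`.
#' @param chunk_size Number of lines read per chunk.
#' @return A `data.frame` with columns `read_id`, `chrom`, `pos` (0-based,
#'   CpG calls on the forward-strand C), `context` (`CpG`, `CHG`, `CHH`,
#'   `unknown`), `methylated` (logical), `strand` (`forward`/`reverse`).
#'   Attributes: `malformed` (skipped record count), `n_data_lines` (data
#'   lines seen).
#' @export
read_bismark_calls <- function(path, strand = c("auto", "forward", "reverse"),
                               chunk_size = 200000L) {
  strand <- match.arg(strand)
  if (!file.exists(path)) {
    stop("extractor file not found: ", path, call. = FALSE)
  }
  if (strand == "auto") {
    strand <- infer_file_strand(path)
    if (is.na(strand)) {
      warning("no OT/OB strand token in filename '", basename(path),
              "'; using CpG calls at their reported positions", call. = FALSE)
      strand <- "forward"
    }
  }
  con <- open_maybe_gz(path)
  on.exit(close(con))

  chunks <- list()
  malformed <- 0L
  n_data <- 0L
  offset <- 0L
  repeat {
    lines <- readLines(con, n = chunk_size, warn = FALSE)
    if (!length(lines)) break
    keep <- !(grepl("^Bismark methylation extractor", lines) | lines == "")
    rel <- which(keep)
    dat <- lines[keep]
    if (length(dat)) {
      n_data <- n_data + length(dat)
      parts <- strsplit(dat, "\t", fixed = TRUE)
      nf <- lengths(parts)
      if (any(nf != 5L)) {
        bad <- which(nf != 5L)[1L]
        stop(sprintf("malformed extractor line %d: expected 5 tab-separated columns, got %d",
                     offset + rel[bad], nf[bad]), call. = FALSE)
      }
      m <- matrix(unlist(parts, use.names = FALSE), ncol = 5L, byrow = TRUE)
      state <- m[, 2L]
      letter <- m[, 5L]
      lower <- tolower(letter)
      context <- unname(CONTEXT_BY_LETTER[lower])
      pos1 <- suppressWarnings(as.integer(m[, 4L]))
      # '−' tolerated as the unmethylated symbol alongside ASCII '-'
      meth_state <- state == "+"
      unmeth_state <- state == "-" | state == "−"
      meth_letter <- letter == toupper(letter)
      ok <- !is.na(context) &
        !is.na(pos1) & pos1 >= 1L &
        ((meth_state & meth_letter) | (unmeth_state & !meth_letter))
      malformed <- malformed + sum(!ok)
      if (any(ok)) {
        chunks[[length(chunks) + 1L]] <- data.table::data.table(
          read_id = m[ok, 1L],
          chrom = m[ok, 3L],
          pos = pos1[ok] - 1L,
          context = context[ok],
          methylated = meth_state[ok]
        )
      }
    }
    offset <- offset + length(lines)
  }
  calls <- if (length(chunks)) {
    as.data.frame(data.table::rbindlist(chunks))
  } else {
    data.frame(read_id = character(0), chrom = character(0), pos = integer(0),
               context = character(0), methylated = logical(0),
               stringsAsFactors = FALSE)
  }
  calls <- normalize_cpg_strand(calls, strand)
  attr(calls, "malformed") <- malformed
  attr(calls, "n_data_lines") <- n_data
  attr(calls, "source") <- path
  calls
}

infer_file_strand <- function(path) {
  nm <- basename(path)
  # CTOB/OB before OT so the complementary tokens match their own strand
  if (grepl("(^|[._])(CTOB|OB)([._]|$)", nm)) return("reverse")
  if (grepl("(^|[._])(CTOT|OT)([._]|$)", nm)) return("forward")
  NA_character_
}

open_maybe_gz <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && identical(magic, as.raw(c(0x1f, 0x8b)))) {
    gzfile(path, open = "rt")
  } else {
    file(path, open = "rt")
  }
}

#' Collapse CpG calls onto the forward-strand cytosine
#'
#' A CpG site spans both strands: the original-bottom (reverse) bisulfite
#' strand reports the site at the G, one base 3' of the forward-strand C.
#' Shifting reverse-strand CpG calls by -1 merges the evidence from both
#' strands at a single coordinate. Non-CpG calls are never shifted.
#'
#' @param calls A calls `data.frame` as returned by [read_bismark_calls()].
#' @param strand `"forward"` or `"reverse"`: the bisulfite strand the calls
#'   were observed on (scalar, or one value per call).
#' @return The calls with `pos` normalized and a `strand` column recording
#'   the original strand.
#' @export
normalize_cpg_strand <- function(calls, strand) {
  stopifnot(all(strand %in% c("forward", "reverse")))
  strand <- rep_len(strand, nrow(calls))
  shift <- strand == "reverse" & calls$context == "CpG"
  calls$pos[shift] <- calls$pos[shift] - 1L
  calls$strand <- strand
  calls
}

#' Write calls in Bismark methylation-extractor format
#'
#' The canonical writer used by the simulator and for round-trip testing.
#' Positions are written 1-based; the state symbol and the call-letter case
#' both encode the methylation state. Calls are written as forward-strand
#' observations (positions as stored), so reading the file back with
#' `strand = "forward"` reproduces the input.
#'
#' @param calls A calls `data.frame` (columns `read_id`, `chrom`, `pos`,
#'   `context`, `methylated`).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param header Whether to write the optional extractor header line.
#' @return `path`, invisibly.
#' @export
write_bismark_calls <- function(calls, path, header = TRUE) {
  letter_by_context <- c(CpG = "z", CHG = "x", CHH = "h", unknown = "u")
  letter <- unname(letter_by_context[calls$context])
  letter[calls$methylated] <- toupper(letter[calls$methylated])
  state <- ifelse(calls$methylated, "+", "-")
  lines <- sprintf("%s\t%s\t%s\t%d\t%s",
                   calls$read_id, state, calls$chrom,
                   as.integer(calls$pos) + 1L, letter)
  if (header) {
    lines <- c("Bismark methylation extractor output (simulated)", lines)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
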