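# Synthetic extractor-file generator with known ground truth.
#
# Emulates what the upstream aligner + methylation extractor would emit for a
# targeted bisulfite amplicon experiment: per-amplicon reads drawn from a
# declared epiallele mixture, per-site dropout, and non-CpG calls whose
# methylation rate models incomplete bisulfite conversion. It does not model
# sequencing error, alignment artifacts, or strand asymmetry (all calls are
# emitted as forward-strand observations).

#' Construct a simulation specification
#'
#' @param amplicons An `amplicon_config` naming the target regions.
#' @param sites Named list (by amplicon name) of 0-based CpG site positions;
#'   every position must lie inside the amplicon's primer-trimmed interval.
#'   An amplicon with an empty site vector models a no-CpG control.
#' @param epiallele_freqs Named list (by amplicon name) of named numeric
#'   vectors mapping full pattern strings (over `{'0','1'}`, one character
#'   per site) to frequencies summing to 1.
#' @param n_reads Reads to draw per amplicon: a single count or a named
#'   vector by amplicon name.
#' @param dropout_rate Per-site probability that a read misses a site, in
#'   `[0, 1]`.
#' @param conversion_error Probability that a non-CpG cytosine appears
#'   methylated (i.e. escaped conversion), in `[0, 1]`.
#' @param n_noncpg Number of non-CpG (CHH/CHG) call lines to emit.
#' @param seed RNG seed; identical seeds give byte-identical output files.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(amplicons, sites, epiallele_freqs, n_reads,
                     dropout_rate = 0, conversion_error = 0.01,
                     n_noncpg = 0L, seed = 1L) {
  spec <- structure(
    list(
      amplicons = amplicons,
      sites = sites,
      epiallele_freqs = epiallele_freqs,
      n_reads = n_reads,
      dropout_rate = dropout_rate,
      conversion_error = conversion_error,
      n_noncpg = as.integer(n_noncpg),
      seed = as.integer(seed)
    ),
    class = "sim_spec"
  )
  validate_sim_spec(spec)
  spec
}

#' Validate a simulation specification
#'
#' Checks structural and numeric invariants; the error message names the
#' offending field.
#'
#' @param spec A `sim_spec` (or a plain list with the same fields).
#' @return `spec`, invisibly, if valid; otherwise an error.
#' @export
validate_sim_spec <- function(spec) {
  fail <- function(field, why) {
    stop(sprintf("invalid simulation spec field '%s': %s", field, why),
         call. = FALSE)
  }
  if (!inherits(spec$amplicons, "amplicon_config") || !nrow(spec$amplicons)) {
    fail("amplicons", "must be a non-empty amplicon_config")
  }
  amps <- spec$amplicons$name
  if (!is.list(spec$sites) || !all(amps %in% names(spec$sites))) {
    fail("sites", "must be a named list covering every amplicon")
  }
  ti <- trimmed_interval(spec$amplicons)
  for (a in amps) {
    s <- spec$sites[[a]]
    t <- ti[ti$name == a, ]
    if (length(s)) {
      if (is.unsorted(s, strictly = TRUE)) fail("sites", paste0(a, ": positions must be strictly increasing"))
      if (any(s < t$trim_start | s >= t$trim_end)) {
        fail("sites", paste0(a, ": positions outside the primer-trimmed interval"))
      }
    }
    f <- spec$epiallele_freqs[[a]]
    if (length(s)) {
      if (is.null(f) || !length(f)) fail("epiallele_freqs", paste0(a, ": missing"))
      if (is.null(names(f)) || any(names(f) == "")) fail("epiallele_freqs", paste0(a, ": patterns must be named"))
      if (any(nchar(names(f)) != length(s))) {
        fail("epiallele_freqs", paste0(a, ": pattern length must equal site count"))
      }
      if (any(grepl("[^01]", names(f)))) {
        fail("epiallele_freqs", paste0(a, ": patterns must be over {0,1}"))
      }
      if (any(f < 0) || abs(sum(f) - 1) > 1e-9) {
        fail("epiallele_freqs", paste0(a, ": frequencies must be non-negative and sum to 1"))
      }
    }
  }
  n <- spec$n_reads
  if (length(n) == 1L && is.null(names(n))) n <- stats::setNames(rep(n, length(amps)), amps)
  if (!all(amps %in% names(n))) fail("n_reads", "must be a single count or named by amplicon")
  if (any(n < 0) || any(n != floor(n))) fail("n_reads", "must be non-negative integers")
  for (fld in c("dropout_rate", "conversion_error")) {
    v <- spec[[fld]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      fail(fld, "must be a single value in [0, 1]")
    }
  }
  if (!is.numeric(spec$n_noncpg) || spec$n_noncpg < 0) fail("n_noncpg", "must be a non-negative count")
  if (!is.numeric(spec$seed) || length(spec$seed) != 1L || is.na(spec$seed)) fail("seed", "must be a single integer")
  invisible(spec)
}

reads_per_amplicon <- function(spec) {
  amps <- spec$amplicons$name
  n <- spec$n_reads
  if (length(n) == 1L && is.null(names(n))) {
    return(stats::setNames(rep(as.integer(n), length(amps)), amps))
  }
  stats::setNames(as.integer(n[amps]), amps)
}

#' Simulate a Bismark-extractor-format file with known truth
#'
#' Draws `n_reads` epialleles per amplicon from the declared mixture, applies
#' per-site dropout, and writes one extractor data line per surviving CpG
#' call (1-based positions, Z/z letters), followed by `n_noncpg` CHH/CHG
#' lines whose methylation rate equals `conversion_error`. A truth table of
#' the drawn epiallele counts is written alongside. The RNG stream is fully
#' determined by `spec$seed` (Mersenne-Twister, rejection sampling), so a
#' fixed seed gives byte-identical files.
#'
#' @param spec A validated `sim_spec`.
#' @param dir Output directory (created if needed).
#' @param basename Stem for the two output files.
#' @return A list: `calls_path`, `truth_path`, and `truth` (data.frame
#'   `amplicon`, `pattern`, `true_count`).
#' @export
simulate_extractor_file <- function(spec, dir, basename = "sim") {
  validate_sim_spec(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n_by_amp <- reads_per_amplicon(spec)
  call_chunks <- list()
  truth_chunks <- list()
  for (k in seq_len(nrow(spec$amplicons))) {
    amp <- spec$amplicons[k, , drop = FALSE]
    class(amp) <- c("amplicon_config", "data.frame")
    a <- amp$name
    sites <- spec$sites[[a]]
    n <- n_by_amp[[a]]
    if (!length(sites) || n == 0L) next
    freqs <- spec$epiallele_freqs[[a]]
    pats <- names(freqs)
    drawn <- sample(seq_along(pats), n, replace = TRUE, prob = as.numeric(freqs))
    tab <- tabulate(drawn, nbins = length(pats))
    truth_chunks[[a]] <- data.frame(
      amplicon = a, pattern = pats, true_count = tab,
      stringsAsFactors = FALSE
    )
    chars <- matrix(unlist(strsplit(pats[drawn], "", fixed = TRUE),
                           use.names = FALSE),
                    nrow = n, byrow = TRUE)
    covered <- if (spec$dropout_rate > 0) {
      matrix(stats::runif(n * length(sites)) >= spec$dropout_rate,
             nrow = n)
    } else {
      matrix(TRUE, nrow = n, ncol = length(sites))
    }
    idx <- which(covered, arr.ind = TRUE)
    if (!nrow(idx)) next
    # one line per surviving call, ordered by read then site
    ord <- order(idx[, 1L], idx[, 2L])
    idx <- idx[ord, , drop = FALSE]
    call_chunks[[a]] <- data.frame(
      read_id = sprintf("%s_r%06d", a, idx[, 1L]),
      chrom = amp$chrom,
      pos = sites[idx[, 2L]],
      context = "CpG",
      methylated = chars[idx] == "1",
      stringsAsFactors = FALSE
    )
  }
  if (spec$n_noncpg > 0L) {
    # non-CpG calls parked on the first amplicon's chromosome at positions
    # clear of any declared CpG site
    amp1 <- spec$amplicons[1L, ]
    all_sites <- unlist(spec$sites, use.names = FALSE)
    pos_pool <- setdiff(seq(amp1$start, amp1$end - 1L), all_sites)
    pos <- pos_pool[((seq_len(spec$n_noncpg) - 1L) %% length(pos_pool)) + 1L]
    context <- ifelse(seq_len(spec$n_noncpg) %% 3L == 0L, "CHG", "CHH")
    call_chunks[["__noncpg__"]] <- data.frame(
      read_id = sprintf("ncpg_r%06d", seq_len(spec$n_noncpg)),
      chrom = amp1$chrom,
      pos = pos,
      context = context,
      methylated = stats::runif(spec$n_noncpg) < spec$conversion_error,
      stringsAsFactors = FALSE
    )
  }
  calls <- if (length(call_chunks)) {
    do.call(rbind, unname(call_chunks))
  } else {
    data.frame(read_id = character(0), chrom = character(0), pos = integer(0),
               context = character(0), methylated = logical(0),
               stringsAsFactors = FALSE)
  }
  calls_path <- file.path(dir, paste0(basename, ".extractor.txt"))
  write_bismark_calls(calls, calls_path)

  truth <- if (length(truth_chunks)) {
    do.call(rbind, unname(truth_chunks))
  } else {
    data.frame(amplicon = character(0), pattern = character(0),
               true_count = integer(0), stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL
  truth_path <- file.path(dir, paste0(basename, ".truth.tsv"))
  con <- file(truth_path, open = "wb")
  writeLines(c(
    sprintf("# amplimeth %s simulation truth table", pkg_version()),
    sprintf("# seed=%d rng=Mersenne-Twister sample.kind=Rejection", spec$seed),
    sprintf("# dropout_rate=%s conversion_error=%s n_noncpg=%d",
            format(spec$dropout_rate), format(spec$conversion_error),
            spec$n_noncpg),
    "amplicon\tpattern\ttrue_count",
    sprintf("%s\t%s\t%d", truth$amplicon, truth$pattern, truth$true_count)
  ), con)
  close(con)
  list(calls_path = calls_path, truth_path = truth_path, truth = truth)
}

# --- JSON (de)serialization of sim specs, used by the CLI -------------------

#' Write a simulation spec as JSON
#' @param spec A `sim_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_spec <- function(spec, path) {
  validate_sim_spec(spec)
  payload <- list(
    amplicons = as.data.frame(spec$amplicons),
    sites = spec$sites,
    epiallele_freqs = lapply(spec$epiallele_freqs, as.list),
    # named vectors must round-trip as JSON objects, not bare arrays
    n_reads = if (is.null(names(spec$n_reads))) spec$n_reads
              else as.list(spec$n_reads),
    dropout_rate = spec$dropout_rate,
    conversion_error = spec$conversion_error,
    n_noncpg = spec$n_noncpg,
    seed = spec$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a simulation spec from JSON
#' @param path Path to a JSON file written by [write_sim_spec()] (or hand
#'   authored in the same schema).
#' @return A validated `sim_spec`.
#' @export
read_sim_spec <- function(path) {
  if (!file.exists(path)) stop("sim spec not found: ", path, call. = FALSE)
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  amp <- as.data.frame(p$amplicons, stringsAsFactors = FALSE)
  need <- c("name", "chrom", "start", "end", "fwd_primer_len", "rev_primer_len")
  if (!all(need %in% names(amp))) {
    stop("invalid simulation spec field 'amplicons': missing columns ",
         paste(setdiff(need, names(amp)), collapse = ", "), call. = FALSE)
  }
  amp$start <- as.integer(amp$start); amp$end <- as.integer(amp$end)
  amp$fwd_primer_len <- as.integer(amp$fwd_primer_len)
  amp$rev_primer_len <- as.integer(amp$rev_primer_len)
  class(amp) <- c("amplicon_config", "data.frame")
  sites <- lapply(p$sites, as.integer)
  freqs <- lapply(p$epiallele_freqs, function(f) unlist(f))
  n_reads <- if (length(p$n_reads) > 1L || !is.null(names(p$n_reads))) {
    unlist(p$n_reads)
  } else {
    as.integer(p$n_reads)
  }
  sim_spec(
    amplicons = amp, sites = sites, epiallele_freqs = freqs,
    n_reads = n_reads,
    dropout_rate = p$dropout_rate %||% 0,
    conversion_error = p$conversion_error %||% 0.01,
    n_noncpg = p$n_noncpg %||% 0L,
    seed = p$seed %||% 1L
  )
}
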