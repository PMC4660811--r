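# Shared builders for in-code fixtures.

make_config <- function(name = "amp1", chrom = "chr1", start = 100L,
                        end = 200L, fwd = 0L, rev = 0L) {
  cfg <- data.frame(
    name = name, chrom = chrom, start = as.integer(start),
    end = as.integer(end), fwd_primer_len = as.integer(fwd),
    rev_primer_len = as.integer(rev), stringsAsFactors = FALSE
  )
  class(cfg) <- c("amplicon_config", "data.frame")
  cfg
}

make_calls <- function(read_id, pos, methylated, context = "CpG",
                       chrom = "chr1", strand = "forward") {
  n <- max(length(read_id), length(pos), length(methylated))
  data.frame(
    read_id = rep_len(read_id, n),
    chrom = rep_len(chrom, n),
    pos = as.integer(rep_len(pos, n)),
    context = rep_len(context, n),
    methylated = rep_len(methylated, n),
    strand = rep_len(strand, n),
    stringsAsFactors = FALSE
  )
}

panel_config <- function() {
  read_amplicon_config(
    system.file("extdata", "amplicon_panel_hg38.tsv", package = "amplimeth"),
    coordinate_style = "ucsc"
  )
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

cli_script <- function() {
  system.file("cli", "amplimeth.R", package = "amplimeth")
}

run_cli <- function(args) {
  out <- suppressWarnings(system2(rscript_bin(), c(cli_script(), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
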