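---
title: "Counting epialleles from bisulfite amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting epialleles from bisulfite amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplimeth)
```

## The model

Bisulfite treatment converts unmethylated cytosine to uracil (read as T)
while 5-methylcytosine is protected, so a bisulfite sequencing read is a
direct readout of the methylation states of one DNA molecule. A CpG site
spans both strands; the original-bottom bisulfite strand reports the site at
the guanine, one base 3' of the forward-strand cytosine, and is collapsed
onto that cytosine here so both strands contribute evidence to a single
coordinate.

For a PCR amplicon with CpG sites $s_1 < \dots < s_k$, each read $r$ defines
an *epiallele* string $p(r) \in \{0, 1, -\}^k$: `1` where the read carries a
methylated call, `0` unmethylated, `-` where the read does not cover the
site. The summary of a sample at one amplicon is the multiset of these
strings: distinct patterns with their read counts and frequencies. This is
strictly more informative than the per-site methylation fraction
$\bar m_j = \Pr(\text{read methylated at } s_j \mid \text{read covers } s_j)$,
which is also reported but averages over molecules and hides allelic and
cell-population structure. No statistical model is fitted: the output is the
observed empirical distribution of patterns, which at amplicon-seq depths
(typically $10^3$–$10^5$ reads per target) estimates the underlying epiallele
frequencies with binomial error $\sqrt{f(1-f)/n}$.

## Inputs and their conventions

**Amplicon configuration.** A BED-like tab-separated file: `chrom`, `start`,
`end`, `name`, and optionally forward/reverse primer lengths (defaulting to 0
with a warning, so plain 4-column BED works). Internally all coordinates are
0-based half-open; `coordinate_style = "ucsc"` accepts 1-based fully-closed
spans as printed by genome browsers and converts once on input, which avoids
off-by-one drift anywhere downstream. Primer-annealing ends of an amplicon
carry the primer's bases rather than the template's methylation, so CpG sites
are only scored inside `[start + fwd_primer_len, end - rev_primer_len)`.
The packaged 48-amplicon hg38 panel records the genome-annealing primer
lengths (sequencing adapters excluded); rows whose public source gives no
coordinates carry clearly documented placeholder spans, listed in the file
header — they exercise the parser but have no genomic meaning.

**Methylation calls.** The Bismark methylation-extractor format: one line per
cytosine per read (`read_id`, `+`/`-` state, chromosome, 1-based position,
call letter `Z/z` CpG, `X/x` CHG, `H/h` CHH, `U/u` unknown, with case
repeating the state). Files are parsed in fixed-size chunks so memory stays
bounded on arbitrarily large inputs. A line with the wrong column count is a
hard error naming the line; a record whose state symbol contradicts its
letter case (or has an unparseable position or letter) is skipped and
counted, so `kept + skipped = data lines` always holds. Unknown-context
calls are parsed but excluded from both patterns and QC.

**Strand designation** comes from the extractor's filename convention
(`OT`/`OB`, `CTOT`/`CTOB`) or an explicit argument; when neither is available
the calls are used at their reported positions with a warning. How the
original workflow merged the two bisulfite strands is not externally
specified, so the collapse rule (reverse-strand CpG shifted by −1) is this
package's documented choice; it is exact for genuine CpG dyads.

## Site discovery and the counting rules

CpG sites are discovered *empirically*: the site index of an amplicon is the
sorted union of observed CpG call positions inside its trimmed interval. The
upstream flow hands this tool only the extractor file and the amplicon
definitions — no reference FASTA — so a reference-derived CpG map is an
extension point, not a dependency. A consequence worth knowing: a site
covered by zero reads in a sample simply does not appear in that sample's
index. An amplicon with no CpG calls at all gets an empty index; that is the
expected behaviour of the no-CpG control amplicon included in conversion
controls, and it renders as an explicit notice rather than an error.

Counting applies three deliberate rules:

* **Coverage filter.** `min_coverage_fraction` (default 1.0) drops reads
  covering fewer than that fraction of sites. Full-length epialleles are the
  interpretable unit — a `1-01` fragment is compatible with two different
  epialleles — so the default counts only complete patterns; lower thresholds
  retain `-`-containing strings as distinct patterns, and the dropped count
  is always reported.
* **Duplicates.** Two calls for the same (read, site) — overlapping
  paired-end mates — resolve first-seen-wins, deterministically; disagreeing
  duplicates are counted as conflicts in QC.
* **Ordering.** Rows are ranked by count descending with a lexicographic
  tie-break on the pattern string, so outputs are identical across runs and
  platforms; reads spanning adjacent amplicons contribute independently to
  each.

Per-site methylation fractions use covering reads only (`-` excluded from
the denominator) and are `NA` at sites no kept read covers.

## Conversion QC

Non-CpG methylation is negligible in human somatic DNA, so the fraction of
CHG+CHH calls read as unmethylated estimates bisulfite conversion
efficiency. The report gives the pooled rate, a per-context breakdown, and
the malformed-record and duplicate-conflict tallies. With zero non-CpG calls
the rate is undefined and flagged rather than silently 0 or 1.

## Outputs

The TSV has `#` metadata lines (tool and format version, run parameters),
then one row per (amplicon, pattern): sample, amplicon, coordinates, site
count and positions, pattern, raw count, and fraction to six decimals. The
HTML file is a single static document — inline styling, no external scripts
or fetches, viewable offline in any browser — drawing one grid per amplicon
(columns: CpG sites; rows: patterns in rank order; three visual cell states
so partial reads remain visible; per-row counts and percentages; a per-site
methylation track) plus a QC panel. The complete summary list is embedded in
a `<script type="application/json">` data island, and `read_html_data()`
recovers it losslessly, so the visualization doubles as an archive of its
own numbers. Percentages printed in the two outputs agree to four decimals
by construction.

## The simulator and what it does (and does not) emulate

`sim_spec()` declares, per amplicon: CpG site positions, a map from full
pattern strings to frequencies (summing to 1 within $10^{-9}$), and a read
count; globally: a per-site dropout probability, a conversion error rate
(probability a non-CpG cytosine appears methylated), a non-CpG call count,
and a seed. `simulate_extractor_file()` draws each read's epiallele from the
mixture, applies independent per-site dropout, and writes extractor-format
lines plus a truth table of drawn counts. The RNG is pinned
(Mersenne–Twister, rejection sampling) and recorded in the truth-table
metadata, so a fixed seed yields byte-identical files.

The simulator emulates the *data structure* the pipeline consumes — mixture
sampling, missingness, incomplete conversion — and with dropout 0 and the
default coverage filter the pipeline recovers the truth table exactly, which
is the basis of the end-to-end tests. It does not model sequencing error,
alignment artifacts, chimeric reads, strand asymmetry, or PCR amplification
bias; passing tests therefore certify the summarization logic, not the
robustness of any upstream alignment.

## Numerical and design choices

* Internal coordinates 0-based half-open everywhere; conversion happens
  exactly once, at input parsing.
* Tie-breaks and duplicate resolution are deterministic (lexicographic;
  first-seen), so repeated runs are byte-identical — asserted in tests.
* Degenerate inputs are legal, not errors: empty extractor files, amplicons
  with zero matching calls, empty site sets, and summaries emptied by the
  coverage filter all produce structurally valid (header-only or
  zero-count) outputs.
* The sampler draws epialleles with `sample(..., prob)` per read; truth
  tables are tabulations of the drawn indices, so truth and emitted calls
  cannot disagree.
* Problem sizes in the test suite were chosen to make sampling error
  negligible relative to the 3-standard-error acceptance bands: $10^4$ reads
  for mixture recovery, $10^4$ non-CpG calls for QC consistency, 200 random
  fixtures of at most 50 reads × 8 sites for oracle equivalence, and one
  $10^6$-line file for the streaming-parser conservation check.

## Known limitations

* Site discovery cannot distinguish a CpG site absent from the genome from
  one merely unobserved in the sample; comparing site indices across samples
  of very different depth requires care.
* Patterns are keyed by observed call positions, so a variant destroying a
  CpG (e.g. a C>T SNP) appears as a constitutively unmethylated column
  rather than being genotype-resolved.
* One sample per invocation, matching the per-sample output files; batching
  is a shell loop by design.
* The HTML grid truncates very long pattern lists for readability (default
  50 rows per amplicon); the data island always contains the full summary.
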