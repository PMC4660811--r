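{
  "amplicons": [
    {
      "name": "mandatory01",
      "chrom": "chr4",
      "start": 154710459,
      "end": 154710544,
      "fwd_primer_len": 26,
      "rev_primer_len": 23
    },
    {
      "name": "uniq_noCG_1",
      "chrom": "chr5",
      "start": 1100000,
      "end": 1100150,
      "fwd_primer_len": 27,
      "rev_primer_len": 33
    }
  ],
  "sites": {
    "mandatory01": [154710488, 154710496, 154710505, 154710512],
    "uniq_noCG_1": []
  },
  "epiallele_freqs": {
    "mandatory01": {
      "1111": 0.55,
      "0000": 0.3,
      "1100": 0.15
    },
    "uniq_noCG_1": []
  },
  "n_reads": {
    "mandatory01": 500,
    "uniq_noCG_1": 0
  },
  "dropout_rate": 0.02,
  "conversion_error": 0.01,
  "n_noncpg": 2000,
  "seed": 42
}
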