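{
  "master_seed": 2024,
  "beta": 0.5,
  "completeness": 1,
  "n_per_cross": 50,
  "repetitions": 1,
  "runs": {
    "subA_rep1": {
      "subline": "subA",
      "repetition": 1,
      "scheme": "acos",
      "homozygous_lethal": false,
      "seed": 2042318,
      "status": "completed",
      "aborted_step": {}
    },
    "subB_rep1": {
      "subline": "subB",
      "repetition": 1,
      "scheme": "acos",
      "homozygous_lethal": true,
      "seed": 2042419,
      "status": "aborted",
      "aborted_step": "F7"
    },
    "gruulA_rep1": {
      "subline": "gruulA",
      "repetition": 1,
      "scheme": "agoc_acos",
      "homozygous_lethal": false,
      "seed": 2042520,
      "status": "aborted",
      "aborted_step": "F9"
    }
  }
}
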