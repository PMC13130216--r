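# Synthetic-mode pipeline configuration used by the examples.
seed: 20240101
out_dir: faersignal-output
synthetic:
  n_reports: 5000
  duplicate_rate: 0.1
thresholds:
  min_cases: 3
  valid_min_algorithms: 2
top_k: 30
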