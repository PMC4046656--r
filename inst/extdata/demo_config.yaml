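# Packaged demo: a small seeded simulated two-tissue run exercising every
# pipeline stage. out_dir is usually overridden at run time.
out_dir: estprofiler_demo
simulate: true
use_slim: true
evalue_threshold: 1.0e-20
sim:
  n_genes: 60
  library_sizes:
    fruit: 50000
    az: 50000
  phi: 0.1
  de_fraction: 0.2
  logfc_effect: 2
  exclusive_fraction: 0.25
  seed: 20
params:
  phi: 0.1
  alpha: 0.01
  pseudocount: 0.5
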