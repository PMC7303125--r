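# Example run configuration: generate a default phantom, derive thresholds
# by ROC between the BMAT-rich and BMAT-deficient marrow regions, quantify.
mode: simulate
seed: 1
deriveThresholds: yes
suv:
  injectedDose: 185    # MBq
  bodyMass: 60000      # g
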