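# Published fitted kinetic constants for the WT GacA homodimer.
# "cooperative": distinct first/second binding events (best-fit model).
# "noncooperative": first and second binding constants forced equal
# (reference model; fits the product-ratio data much worse).
# Units: dissociation constants in micromolar, kcat in per second.
version: 1
presets:
  cooperative:
    K1A: 343
    K2A: 53
    K1G: 39
    K2G: 20
    KAG: 71
    KGA: 10
    kcat_cdiA: 0.03
    kcat_cdiG: 0.03
    kcat_cGAMP: 0.03
  noncooperative:
    K1A: 80
    K2A: 80
    K1G: 25
    K2G: 25
    KAG: 80
    KGA: 25
    kcat_cdiA: 0.04
    kcat_cdiG: 0.04
    kcat_cGAMP: 0.04
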