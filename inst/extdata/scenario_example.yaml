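# Example scenario file for load_scenario(): an intermediate-depth water
# body between the built-in fast and slow cases, with the aqueous IBAP
# removal split into its photochemical pathways (day^-1 throughout).
k_d: 0.1
k_f: 0.02
k_d_prime: 0.12
k_vol: 0.052
k_g: 0.46
pathway_split:
  k_OH_w: 0.03
  k_3CDOM: 0.05
  k_dp: 0.04
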