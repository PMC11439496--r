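seeds_fasta: seeds.fasta
families:
- name: METE
  special_rule: mete_arabidopsis
  required_domains:
  - PF08267
  - PF01717
  seeds:
  - METE_seed1
  - METE_seed2
- name: METH
  special_rule: none
  required_domains:
  - PF02574
  - PF00809
  - PF02607
  - PF02310
  - PF02965
  seeds:
  - METH_seed1
  - METH_seed2
- name: MTRR
  special_rule: none
  required_domains:
  - PF00258
  - PF00667
  - PF00175
  seeds:
  - MTRR_seed1
  - MTRR_seed2
- name: MCM
  special_rule: none
  required_domains:
  - PF01642
  - PF02310
  seeds:
  - MCM_seed1
  - MCM_seed2
- name: RNR-II
  special_rule: none
  required_domains:
  - PF02867
  seeds:
  - RNR-II_seed1
  - RNR-II_seed2
- name: CblA
  special_rule: none
  required_domains:
  - PF03308
  seeds:
  - CblA_seed1
  - CblA_seed2
- name: CblB
  special_rule: none
  required_domains:
  - PF01923
  seeds:
  - CblB_seed1
  - CblB_seed2
- name: CblC
  special_rule: none
  required_domains:
  - PF16690
  seeds:
  - CblC_seed1
  - CblC_seed2
- name: CblD
  special_rule: none
  required_domains:
  - PF10229
  seeds:
  - CblD_seed1
  - CblD_seed2
- name: CblF
  special_rule: none
  required_domains:
  - PF04791
  seeds:
  - CblF_seed1
  - CblF_seed2
- name: CblJ
  special_rule: none
  required_domains:
  - PF00005
  seeds:
  - CblJ_seed1
  - CblJ_seed2
- name: CblX
  special_rule: none
  required_domains:
  - PF13415
  seeds:
  - CblX_seed1
  - CblX_seed2
- name: epi-CblC
  special_rule: none
  required_domains:
  - PF16690
  seeds:
  - epi-CblC_seed1
  - epi-CblC_seed2
- name: CBA1
  special_rule: cba1_consensus
  required_domains: []
  seeds:
  - CBA1_seed1
  - CBA1_seed2
domain_seeds_fasta: domain_seeds.fasta
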