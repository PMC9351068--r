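chromosomes:
- name: chr1
  length: 10000000
  centromere_start: 4000000
  centromere_end: 4500000
- name: chr2
  length: 10000000
  centromere_start: 4000000
  centromere_end: 4500000
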