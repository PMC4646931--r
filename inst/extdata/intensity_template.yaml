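fragment_rich:
  '40':
    precursor: 2.0
    fa_anion: 100.0
    hfa_anion: 25.0
    hfa_dehydrated: 20.0
    positional_tail: 0.2
    positional_head: 0.1
profiling:
  '10':
    precursor: 100.0
    fa_anion: 30.0
    hfa_anion: 10.0
    hfa_dehydrated: 5.0
  '20':
    precursor: 40.0
    fa_anion: 100.0
    hfa_anion: 30.0
    hfa_dehydrated: 15.0
  '40':
    precursor: 2.0
    fa_anion: 100.0
    hfa_anion: 25.0
    hfa_dehydrated: 20.0
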