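# Named simulation scenarios. Presets are immutable: edit a copy, not this file.
paper_mimic:
  description: >
    Two oligomer populations with FRET-efficiency components centred at 0.24
    (loosely packed, Type-A-like) and 0.48 (compact, Type-B-like), 60/40
    weights, component spread 0.08. Expected 5,000 events over a 600 s
    acquisition binned at 1 ms.
  species:
    - name: type_a
      size: 6
      efficiency: 0.24
      efficiency_sd: 0.08
      weight: 0.6
      brightness_per_monomer: 50
    - name: type_b
      size: 6
      efficiency: 0.48
      efficiency_sd: 0.08
      weight: 0.4
      brightness_per_monomer: 50
  instrument:
    autofluor_donor: 2
    autofluor_acceptor: 2
    crosstalk: 0.05
    gamma: 1.0
  event_rate: 8.333333333
  duration: 600
  bin_width: 0.001
monomer_only:
  description: >
    Donor-only monomeric species (no FRET): acceptor-channel signal arises
    solely from cross-talk and background. Used for monomer-brightness and
    chance-coincidence baselines.
  species:
    - name: monomer
      size: 1
      efficiency: 0.0
      efficiency_sd: 0.0
      weight: 1.0
      brightness_per_monomer: 50
  instrument:
    autofluor_donor: 2
    autofluor_acceptor: 2
    crosstalk: 0.05
    gamma: 1.0
  event_rate: 8.333333333
  duration: 600
  bin_width: 0.001
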