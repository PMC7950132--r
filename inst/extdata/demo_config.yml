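# Demo ground-truth experiment: a 120-residue synthetic protein in two
# states; the bound state loses one log unit of protection over
# residues 60-75. Labelling design mirrors a short-timescale HDX-MS
# experiment: 15/30/45/60/120 s, 3 technical replicates, 25% back
# exchange, 0.02 Da centroid noise.
protein: demo1
sequence: VLGAQMYWGDMDLNHTNMTTADKHGSCDDCHKCIKCLWDCMAEYMCGWWICKCILQRVEIFMLEKFGECRNLWYFQDLWADGQHDFKLIGWSQGMCNTMRSSLMSWKRNYRYHLHWFWVA
states:
  - name: apo
    default_log10_P: 4
  - name: bound
    default_log10_P: 4
    regions:
      - {start: 60, end: 75, log10_P: 3}
back_exchange: 0.25
noise_sd: 0.02
timepoints: [15, 30, 45, 60, 120]
n_replicates: 3
disordered_termini: 10
map: {target_length: 10, overlap: 5}
digly:
  occupancy: {K23: 0.5, K87: 0.3}
  n_peptides_per_site: 20
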