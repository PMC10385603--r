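{
  "name": "Cu-64",
  "half_life_h": 12.7004,
  "branch_beta_plus": 0.174,
  "branch_beta_minus": 0.390,
  "branch_ec": 0.44,
  "mean_energy_beta_minus_mev": 0.1902,
  "mean_energy_beta_plus_mev": 0.2782,
  "mean_energy_auger_ce_mev": 0.004,
  "mean_energy_np_mev": 0.1265848,
  "mean_energy_photon_mev": 0.1842,
  "source_citation": "Half-life 12.7004 h and mean decay energies per ICRP Publication 107 nuclear decay data (beta- mean 0.1902 MeV at 39.0%, beta+ mean 0.2782 MeV at 17.4%, Auger/conversion electrons ~0.004 MeV/decay; photons = annihilation 0.174 x 1.022 MeV + 1.3459 MeV gamma at 0.475%). Branching fractions stored exactly as commonly quoted (beta+ 17.4%, beta- 39.0%, EC 44%); their sum is 1.004 and is deliberately not renormalised."
}
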