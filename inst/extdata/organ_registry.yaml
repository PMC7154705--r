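# Tree-organ composition and turnover registry.
#
# Shares are fractions of total standing biomass per organ (must sum to 1
# within each species group); turnover rates are 1/yr natural transfers to
# litter. Values are temperate-forest defaults in the FORCLIM-D / Liski
# tradition; they are replaceable data, not code. `extracted` marks the
# organs that make up commercial wood (stem and large branches).
carbon_fraction: 0.47        # t C per t dry matter
wood_density:                # t dry matter per m3 overbark
  deciduous: 0.55
  coniferous: 0.42
branch_residue_ratio: 0.10   # non-harvested : harvested branch material at felling
groups:
  deciduous:
    organs:
      leaves:         {share: 0.03, turnover: 1.00, extracted: false}
      small_branches: {share: 0.08, turnover: 0.025, extracted: false}
      large_branches: {share: 0.14, turnover: 0.010, extracted: true}
      stem:           {share: 0.55, turnover: 0.005, extracted: true}
      large_roots:    {share: 0.17, turnover: 0.010, extracted: false}
      fine_roots:     {share: 0.03, turnover: 0.800, extracted: false}
  coniferous:
    organs:
      leaves:         {share: 0.06, turnover: 0.22, extracted: false}
      small_branches: {share: 0.08, turnover: 0.025, extracted: false}
      large_branches: {share: 0.12, turnover: 0.010, extracted: true}
      stem:           {share: 0.52, turnover: 0.005, extracted: true}
      large_roots:    {share: 0.17, turnover: 0.010, extracted: false}
      fine_roots:     {share: 0.05, turnover: 0.800, extracted: false}
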