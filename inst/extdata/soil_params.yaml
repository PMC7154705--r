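# Litter and humus decay registry.
#
# Foliage and fine-root base rates are multiplied by the climate modifier
# phi = 1 + 0.094 (T - 4) + 0.0023 (M + 50); the woody pools decay at fixed
# registry rates. Humification fractions route a share of each litter decay
# flux into the fast humus pool; the remainder is mineralised as CO2.
litter:
  foliage:              {base_decay: 0.35, climate_sensitive: true,  humification: 0.20}
  fine_roots:           {base_decay: 0.25, climate_sensitive: true,  humification: 0.20}
  coarse_woody:         {base_decay: 0.05, climate_sensitive: false, humification: 0.20}
  large_roots_branches: {base_decay: 0.10, climate_sensitive: false, humification: 0.20}
climate_modifier_floor: 0.05   # phi never falls below this (cold/dry guard)
fast_humus:
  a0: 0.04        # /yr reference decay rate (~25-year turnover)
  t_ref: 10       # degC anchor temperature
  q10: 2.0        # exponential temperature response a = a0 * q10^((T - t_ref)/10)
slow_humus:
  decay_factor: 0.007        # printed constant pair; role assignment below
  transfer_fraction: 0.0033
  # ratio_consistent: slow decay = transfer_fraction * a, fed by decay_factor
  #   of fast decay, so steady-state slow:fast = 0.007/0.0033 ~ 2.1
  # literal: the reverse role assignment (sentence order), ratio ~ 0.47
  wiring: ratio_consistent
# Organ -> litter-pool mapping (harvest residues and natural mortality)
organ_pools:
  leaves: foliage
  small_branches: foliage
  fine_roots: fine_roots
  stem: coarse_woody
  large_branches: large_roots_branches
  large_roots: large_roots_branches
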