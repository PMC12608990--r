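# National demographic reference used for emergent (non-quota) population
# generation and for "demographic-curve" age sampling inside group specs.
# Age weights approximate the Spanish population pyramid in 5-year bins;
# ages are drawn from a piecewise-linear density through the bin midpoints.
age_bins:
  - {lo: 0,  hi: 5,  weight: 4.0}
  - {lo: 5,  hi: 10, weight: 4.6}
  - {lo: 10, hi: 15, weight: 5.0}
  - {lo: 15, hi: 20, weight: 5.0}
  - {lo: 20, hi: 25, weight: 5.0}
  - {lo: 25, hi: 30, weight: 5.1}
  - {lo: 30, hi: 35, weight: 5.4}
  - {lo: 35, hi: 40, weight: 6.0}
  - {lo: 40, hi: 45, weight: 7.5}
  - {lo: 45, hi: 50, weight: 8.0}
  - {lo: 50, hi: 55, weight: 7.7}
  - {lo: 55, hi: 60, weight: 7.2}
  - {lo: 60, hi: 65, weight: 6.5}
  - {lo: 65, hi: 70, weight: 5.6}
  - {lo: 70, hi: 75, weight: 4.8}
  - {lo: 75, hi: 80, weight: 3.9}
  - {lo: 80, hi: 85, weight: 2.9}
  - {lo: 85, hi: 100, weight: 3.2}
pct_female: 51
pct_coastal: 45
locality_shares: {small: 28, medium: 37, large: 35}
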