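meta:
  name: bundled-baseline
horizon:
  start: 2008
  end: 2025
supply_params:
  numerus_clausus:
    '2008': 600.0
  retirement_age:
    '2008': 65.0
  carry_forward: yes
  sex_split: 0.66666666666666663
demand_params:
  base_year: 2008
  population_scenario: moderate
files:
  initial_stock: initial_stock.csv
  mortality: mortality.csv
  dropout: dropout.csv
  fte: fte.csv
  standards: standards.csv
  positions: positions.csv
  population: population.csv
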