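# Six genetic/genomic testing strategies for rare developmental
# disorders, NHS Scotland. Costs in 2022 GBP, VAT inclusive; yields are
# context-specific diagnostic yields (proportion of tested patients
# diagnosed). Stage proceed_prob / extra_cost are calibration slots for
# pathway detail (branch probabilities, clinic visits) beyond the
# simplified tree; they default to neutral values.
name: scotland_base
currency: GBP
cost_year: 2022
settings:
  discount_rate: 0.035
  horizon_years: 3
tests:
- id: cma_fx
  label: 1st-line chromosomal microarray and Fragile X testing
  cost:
    mean: 386.0
    ci: [358.0, 414.0]
    family: gamma
  yields:
    first_line:
      mean: 0.10
      ci: [0.09, 0.12]
      family: beta
- id: panels
  label: 2nd-line single gene tests and gene panels
  cost:
    mean: 2275.0
    ci: [1836.0, 2948.0]
    family: gamma
  yields:
    second_line:
      mean: 0.21
      ci: [0.14, 0.29]
      family: beta
- id: gs
  label: Trio genome sequencing
  cost:
    mean: 5576.0
    ci: [5018.0, 6133.0]
    family: gamma
  yields:
    first_line:
      mean: 0.46
      ci: [0.36, 0.57]
      family: beta
    second_line:
      mean: 0.40
      ci: [0.33, 0.47]
      family: beta
    last_resort:
      mean: 0.23
      ci: [0.14, 0.32]
      family: beta
- id: es
  label: Trio exome sequencing
  cost:
    mean: 1153.0
    ci: [1060.0, 1245.0]
    family: gamma
  yields:
    second_line:
      mean: 0.37
      ci: [0.27, 0.49]
      family: beta
    last_resort:
      mean: 0.21
      ci: [0.13, 0.29]
      family: beta
strategies:
- name: Standard genetic testing
  stages:
  - {test: cma_fx, context: first_line, year: 1, proceed_prob: 1.0, extra_cost: 0.0}
  - {test: panels, context: second_line, year: 2, proceed_prob: 1.0, extra_cost: 0.0}
- name: 1st-line GS
  stages:
  - {test: gs, context: first_line, year: 1, proceed_prob: 1.0, extra_cost: 0.0}
- name: 2nd-line GS
  stages:
  - {test: cma_fx, context: first_line, year: 1, proceed_prob: 1.0, extra_cost: 0.0}
  - {test: gs, context: second_line, year: 2, proceed_prob: 1.0, extra_cost: 0.0}
- name: Last-resort GS
  stages:
  - {test: cma_fx, context: first_line, year: 1, proceed_prob: 1.0, extra_cost: 0.0}
  - {test: panels, context: second_line, year: 2, proceed_prob: 1.0, extra_cost: 0.0}
  - {test: gs, context: last_resort, year: 3, proceed_prob: 1.0, extra_cost: 0.0}
- name: 2nd-line ES
  stages:
  - {test: cma_fx, context: first_line, year: 1, proceed_prob: 1.0, extra_cost: 0.0}
  - {test: es, context: second_line, year: 2, proceed_prob: 1.0, extra_cost: 0.0}
- name: Last-resort ES
  stages:
  - {test: cma_fx, context: first_line, year: 1, proceed_prob: 1.0, extra_cost: 0.0}
  - {test: panels, context: second_line, year: 2, proceed_prob: 1.0, extra_cost: 0.0}
  - {test: es, context: last_resort, year: 3, proceed_prob: 1.0, extra_cost: 0.0}
scenarios:
  low_gs:
    tests.gs.cost.mean: 3781.0
    tests.gs.cost.ci: [3403.0, 4159.0]
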