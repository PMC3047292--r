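# Example simulation run: three practices of different sizes, one with a
# two-week software downtime, default staff behaviour, suppression off.
seed: 42
target: 200
size_threshold: 600
study:
  start: 2007-05-01
  months: 12
staff:
  p_respond: 0.064
  p_exclude_given_respond: 0.6294
  p_refuse_given_contact: 0.2023
  p_interrupt_given_start: 0.0274
suppression:
  enabled: false
  tolerance: 5
  min_enrolled: 50
practices:
  - practice_id: P01
    panel_size: 650
    visit_rate: 0.5
    not_present_prob: 0.2
  - practice_id: P02
    panel_size: 420
    visit_rate: 0.5
    downtime:
      - start: 2007-09-01
        end: 2007-09-14
  - practice_id: P03
    panel_size: 980
    visit_rate: 0.6
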