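id: id
visit: visit
treatment: A
event_time: event_time
event_indicator: event_indicator
l_cols:
  - L
p_cols:
  - P
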