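# Ordered lithology -> level-1 habitat rules; first match wins.
# Categories: stagnant, low-velocity, medium-velocity, high-velocity, excluded.
- pattern: cave
  category: excluded
  note: karst infill, no energy signal
- pattern: cross-stratified sandstone
  category: high-velocity
  note: bedform transport, bumped one class up
- pattern: conglomerate
  category: high-velocity
  note: coarse clastic
- pattern: sandstone
  category: medium-velocity
  note: medium grain
- pattern: siltstone
  category: low-velocity
  note: fine grain
- pattern: claystone
  category: stagnant
  note: suspension settling
- pattern: coal
  category: stagnant
  note: still-water organic
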