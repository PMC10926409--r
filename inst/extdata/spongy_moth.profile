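# Spongy moth (Lymantria dispar) adult-emergence profile.
# Staged thresholds in degrees C; degree-day requirements in C-days.
name: spongy_moth
start_date: 01-01
stage: egg lower=3 upper=38 dd=282
stage: larvae lower=7.2 upper=41 dd=583
stage: pupae lower=6.6 upper=41 dd=277
event: adult_emergence 1143
event: flight_end 1528
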