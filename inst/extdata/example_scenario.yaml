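# Synthetic weather scenario: temperate station, two decades.
mean_annual: 12
seasonal_amplitude: 11
diurnal_range: 9
noise_sd: 2.5
noise_autocorr: 0.6
precip_rate: 2.5
years: [2001, 2002, 2003, 2004, 2005]
grid_shape: [1, 1]
lat0: 40
seed: 20
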