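# Oak ambrosia beetle (Platypus quercivorus) climate-suitability profile.
# Lethal limit = supercooling point minus tree-interior insulation.
name: oak_ambrosia_beetle
start_date: 01-01
generation: lower=11.1 upper=38 dd=1486
lethal: supercooling_point=-20.3 insulation=1.2
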