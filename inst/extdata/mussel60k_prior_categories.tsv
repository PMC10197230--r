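category	n_markers
species_id	12
sex	140
cancer1	301
cancer2	35
structure	113
structure_fluidigm	113
structure_chilensis	96
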