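category	n_markers
shared_all	3268
shared_3	13185
shared_2	37554
exclusive:galloprovincialis	1339
exclusive:edulis	1384
exclusive:chilensis	1361
exclusive:trossulus	1360
prior	691
total	60142
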