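species	n_individuals	total	monomorphic	polymorphic	unique_polymorphic
galloprovincialis	30	20504	2317	18187	5100
edulis	22	23252	2637	20888	6478
trossulus	14	20149	5190	14959	4526
chilensis	14	22165	3607	18558	5782
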