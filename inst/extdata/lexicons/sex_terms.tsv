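# surface term	canonical sex category	optional suffix expansions
boy	male	s
girl	female	s
man	male
men	male
woman	female
women	female
male	male	s
female	female	s
transgender	transgender
trans	transgender
transgender man	transgender_man
transgender men	transgender_man
transgender woman	transgender_woman
transgender women	transgender_woman
trans man	transgender_man
trans men	transgender_man
trans woman	transgender_woman
trans women	transgender_woman
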