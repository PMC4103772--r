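sequence	count
AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTC	50
GGCCTTTCCATATCTCGTGAACCCCCTGCACGCCCTAAAG	30
TACAATTAGGATATTCATCCCTACACTGTATATGCCGAAC	12
AAAACTCCAGTGTAACTCCGGAAGTAGAATCTTGCACTC	3
GGCCTTTCCATATCTCGTGCACCCCCTGCACGCCCTAAAG	2
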