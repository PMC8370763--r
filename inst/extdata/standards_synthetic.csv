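"name","mass_kda","contrast"
"protein A",42,0.00223576
"ADH dimer",73.5,0.003818005
"beta-amylase dimer",112,0.00575186
"ADH tetramer",147,0.00750991
"beta-amylase tetramer",224,0.01137762
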