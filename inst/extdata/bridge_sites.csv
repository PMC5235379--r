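"name","row","col"
"left_island",4,3
"bridge_mid",4,12
"right_island",4,22
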