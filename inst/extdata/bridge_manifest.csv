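"time_kya","path"
45,"bridge_frame1.asc"
44.6,"bridge_frame2.asc"
44.2,"bridge_frame3.asc"
43.4,"bridge_frame4.asc"
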