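organ	gy_per_mbq	sd_per_mbq	gy_37mbq	sd_37mbq
Tumour	0.6	0.1	21.3	5.0
Liver	0.2	0.0	7.4	0.9
Spleen	0.1	0.0	5.2	0.5
Intestine wall	0.0	0.0	1.5	0.3
Kidneys	0.1	0.0	4.5	0.4
Ganglia	0.0	0.0	0.5	0.1
Lungs	0.0	0.0	1.7	0.4
Heart	0.0	0.0	1.9	0.2
Stomach wall	0.0	0.0	1.2	0.1
Salivary glands	0.0	0.0	0.8	0.1
Bone	0.0	0.0	0.8	0.2
Pancreas	0.0	0.0	0.5	0.0
Brain	0.0	0.0	0.2	0.0
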