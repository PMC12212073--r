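#slow5_version	0.2.0
#num_read_groups	1
#read_id	digitisation	offset	range	sampling_rate	len_raw_signal	raw_signal
read-0001	2048	4	1126.47	5000	8	512,514,511,520,770,768,765,771
read-0002	2048	6.5	1126.47	5000	5	100,101,99,300,298
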