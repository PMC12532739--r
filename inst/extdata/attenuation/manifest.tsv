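symbol	name	atomic_number	density_g_cm3	file
Fe	iron	26	7.87	fe.tsv
Cu	copper	29	8.96	cu.tsv
W	tungsten	74	19.30	w.tsv
Pb	lead	82	11.35	pb.tsv
Bi	bismuth	83	9.78	bi.tsv
water	water	NA	1.00	water.tsv
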