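region	side	mean_tse_mm3	mean_drb_mm3	mean_diff_mm3	sd_diff_mm3
Parasubiculum	right	63.9	64	0.2	1.6
Presubiculum-Head	right	124.4	123.5	-0.9	4
Subiculum-Head	right	186.4	185.8	-0.6	4.2
CA1-Head	right	566	569.9	3.9	9.6
CA2/3-Head	right	137.3	136.9	-0.4	3.7
CA4-Head	right	141.2	139.7	-1.5	2.9
GC-ML-DG-head	right	174.2	172.5	-1.7	3.5
molecular_layer_HP-head	right	323.5	324.6	1.1	10.3
HATA	right	66.1	65.4	-0.6	1.9
Presubiculum-body	right	139.3	140.2	0.9	3.9
Subiculum-body	right	232.9	232.7	-0.3	4.3
CA1-Body	right	133.2	135.2	2	2.6
CA2/3-body	right	92.4	91.5	-0.9	4
CA4-body	right	116.1	113.1	-3	3.3
GC-ML-DG-body	right	129.6	130.5	0.9	20.5
molecular_layer_HP-body	right	250	248.2	-1.8	23.3
fimbria	right	73	74.3	1.4	3.4
Hippocampal_tail	right	564.5	564.7	0.2	6.4
hippocampal-fissure	right	138.8	138.5	-0.4	4.3
Whole_hippocampal_body	right	1166.5	1158.7	-7.8	13.8
Whole_hippocampal_head	right	1782.9	1782.5	-0.4	19.1
Whole_hippocampus	right	3513.9	3505.9	-8	27.8
Parasubiculum	left	66.9	65.9	-1	2.1
Presubiculum-Head	left	128.6	129.5	0.9	5.9
Subiculum-Head	left	188.4	188.3	-0.04	4.2
CA1-Head	left	556.8	559.2	2.4	9.6
CA2/3-Head	left	130	128.7	-1.3	3.5
CA4-Head	left	134.9	134.6	-0.2	3.9
GC-ML-DG-head	left	166.8	166.7	-0.1	4.7
molecular_layer_HP-head	left	341	337.6	-3.4	11.3
HATA	left	67.4	64.6	-2.8	12.8
Presubiculum-body	left	157.2	158.8	1.5	4.7
Subiculum-body	left	250.1	249.3	-0.8	6
CA1-Body	left	130.1	128.9	-1.1	4.3
CA2/3-body	left	89.2	87	-2.2	4.1
CA4-body	left	116.3	114.8	-1.5	3.5
GC-ML-DG-body	left	130.8	130.2	-0.6	4.5
molecular_layer_HP-body	left	239.9	238.2	-1.8	6.9
fimbria	left	72.6	74.9	2.3	4.1
Hippocampal_tail	left	561.7	563.1	1.3	6.4
hippocampal-fissure	left	135.6	137.5	1.9	17.1
Whole_hippocampal_body	left	1186.2	1182	-4.2	15.7
Whole_hippocampal_head	left	1778.6	1777.1	-1.5	19.9
Whole_hippocampus	left	3526.5	3522.1	-4.3	33.6
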