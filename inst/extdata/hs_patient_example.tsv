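region	right_mm3	left_mm3	reported_diff_mm3	reported_z
Parasubiculum	33.0	53.7	-20.7	-0.9
Presubiculum-Head	70.6	108.1	-37.6	-1.9
Subiculum-Head	101.7	148.1	-46.4	-2.3
CA1-Head	251.1	437.4	-186.3	-5.4
CA2/3-Head	62.8	99.8	-37.0	-2.6
CA4-Head	53.4	99.9	-46.5	-3.7
GC-ML-DG-head	67.3	123.1	-55.8	-3.3
molecular_layer_HP-head	151.9	251.8	-99.9	-3.9
HATA	44.7	53.3	-8.6	-1.1
Presubiculum-body	73.2	132.1	-58.9	-1.8
Subiculum-body	121.9	216.7	-94.8	-4.5
CA1-Body	67.2	130.3	-63.1	-3.1
CA2/3-body	39.2	82.3	-43.1	-3.1
CA4-body	40.6	103.4	-62.7	-5.2
GC-ML-DG-body	46.7	117.4	-70.7	-4.7
molecular_layer_HP-body	145.8	239.4	-93.7	-4.0
fimbria	24.4	32.9	-8.5	-0.5
Hippocampal_tail	288.5	486.2	-197.6	-3.5
hippocampal-fissure	101.1	126.3	-25.2	-1.2
Whole_hippocampal_body	559.2	1054.5	-495.3	-6.5
Whole_hippocampal_head	836.5	1375.2	-538.8	-5.2
Whole_hippocampus	1684.2	2915.9	-1231.8	-6.3
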