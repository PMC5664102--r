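pair_label	n_shortest_path_genes	n_candidates	n_inferred
bone--dentin	244	42	4
bone--nerve	514	55	3
bone--vessel	481	72	4
dentin--nerve	417	60	4
dentin--vessel	390	71	8
nerve--vessel	649	72	4
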