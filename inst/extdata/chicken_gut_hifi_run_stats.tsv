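compartment	pacbio_cells	n_reads	n_bases	n50_bp	median_q
Duodenum	1	2734871	22233516165	9778	39
Jejunum	2	2669321	44559115216	16417	35
Ileum	2	4282202	72828594344	16856	33
Cecum	3	5045925	80959163166	17319	31
Colorectum	3	5865946	111891321947	19258	31
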