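# Published worm-yeast essentiality bookkeeping counts (WormBase WS220;
# ortholog pairs from InParanoid; yeast essentials from SGD).
quantity	count
genes_mutated	6013
mutations_total	6841
worm_lethal	1436
single_copy_essential	946
orthologous_pairs	1905
worm_lethal_with_yeast_ortholog	413
yeast_essential	1193
yeast_essential_with_worm_ortholog	678
shared_essential	193
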