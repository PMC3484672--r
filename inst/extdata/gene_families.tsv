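# Multigene-family knockout counts, C. elegans Deletion Mutant Consortium era
# (WormBase WS220 / GExplore gene totals). consortium_mutated = genes with a
# tm, ok, or gk allele.
family	total_genes	mutated_genes	consortium_mutated
ABC transporters	58	57	53
Cadherin family	12	11	9
Calmodulin-like EF hand	70	34	25
Cytochrome p450	75	28	28
Degenerin channels	30	24	21
Epidermal growth factor domain	191	119	98
Fibronectin type III domain	47	37	35
GPCR rhodopsin	139	74	73
GPCR orphan	1307	286	281
Guanylate cyclase domain	38	36	35
Helicases	85	53	46
Heterotrimeric G proteins	22	21	3
Innexins	25	25	21
Kinases	416	380	359
Ligand-gated ion channels	101	63	53
LIM domain	30	25	24
LRR domain	56	26	22
MATH domain	86	70	70
Metalloproteases	46	29	28
microRNA (Mir)	207	92	36
Neuropeptides	114	74	73
Nuclear hormone receptors	275	250	245
PAZ (Argonaute/Dicer family)	26	25	23
PDZ domain	64	41	35
Phosphatases	98	28	21
Potassium channels	72	40	31
RRM (RNA recognition motif)	110	67	56
Transcription factors	941	866	836
TRP (transient receptor potential channel)	21	21	19
Ubiquitin-like	25	14	14
Ubiquitin conjugating enzyme E2	31	15	13
Zinc finger proteins	831	655	627
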