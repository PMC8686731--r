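taxon	order	prev_overall	prev_female	prev_male
Schizocosa saltatrix	Araneae	0.408	0.417	0.388
Arrenurus reflexus	Trombidiformes	0.211	0.155	0.327
Peyerimhoffia vagabunda	Diptera	0.132	0.155	0.082
Macrosteles patruelis	Hemiptera	0.125	0.146	0.082
Ablabesmyia illinoensis	Diptera	0.112	0.126	0.082
Platypalpus sp.	Diptera	0.092	0.097	0.082
Minettia lyraformins	Diptera	0.086	0.087	0.082
Eriosoma americanum	Hemiptera	0.072	0.039	0.143
Schizocosa sp.	Araneae	0.066	0.049	0.102
Smittia sp.	Diptera	0.059	0.049	0.082
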