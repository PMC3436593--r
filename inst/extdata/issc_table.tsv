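# Critical saturation indices, re-derived empirically with
# BarcodeDelim::regenerateIssCritical(nOtus=c(4,8,16,32),
#   lengths=c(200,400,800,1600), nReplicates=40,
#   recoveryTarget=0.95, seed=7).
# Synthetic stand-in for the published simulation tables: the
# critical index is the mean Iss at the deepest JC69 model-tree
# depth at which neighbor joining still attains >= 95% of its
# best bipartition-recovery performance across the depth grid.
n_otu	n_sites	topology	iss_c
4	200	symmetric	0.5909
4	200	asymmetric	0.5244
4	400	symmetric	0.6498
4	400	asymmetric	0.6051
4	800	symmetric	0.6345
4	800	asymmetric	0.6042
4	1600	symmetric	0.6498
4	1600	asymmetric	0.6502
8	200	symmetric	0.7159
8	200	asymmetric	0.6552
8	400	symmetric	0.7339
8	400	asymmetric	0.6517
8	800	symmetric	0.7364
8	800	asymmetric	0.7494
8	1600	symmetric	0.7412
8	1600	asymmetric	0.7529
16	200	symmetric	0.7145
16	200	asymmetric	0.6069
16	400	symmetric	0.8149
16	400	asymmetric	0.7307
16	800	symmetric	0.8229
16	800	asymmetric	0.7375
16	1600	symmetric	0.8268
16	1600	asymmetric	0.7375
32	200	symmetric	0.7669
32	200	asymmetric	0.6794
32	400	symmetric	0.7682
32	400	asymmetric	0.5511
32	800	symmetric	0.7699
32	800	asymmetric	0.6877
32	1600	symmetric	0.7701
32	1600	asymmetric	0.6897
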