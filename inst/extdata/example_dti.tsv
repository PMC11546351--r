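SMILES	Protein	Y
CC(C)CC(=O)O	MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQHKLMAPLDNAVRQSLA	1
CCOC(=O)CC	MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPLDNAVRQSLAWQRS	0
c1ccccc1CCN	GSHMASLEEQVGLMHKLMRRPQGTSLVATTTGSGSNAEKLAALEAKLDD	0
C1CCCCC1CC(=O)O	GSHMASLEEQVGLMHKLMRRPQGTSLVATTTGSGSNAEKLAALEAKLDD	1
NCCOCCN	ADKELKFLVVDDFSTMRRIVRNLLKELGFNNVEEAEDGVDALNKLQAGG	0
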