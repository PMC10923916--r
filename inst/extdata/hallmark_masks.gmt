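macrophage	macrophage mask markers	CD68	CD163	FCGR1A	CSF1R
t_cell	T cell mask markers	CD3D	CD3E	UBASH3A	CD2	TRBC2
b_cell	B cell mask markers	MS4A1	CD79A	CD79B	CD19	PAX5
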