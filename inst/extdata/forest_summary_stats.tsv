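# Published summary statistics (averaged over census years) for three
# Centre for Tropical Forest Science 50-ha plots.
forest	J	S	shannon
BCI	21058	232	4.275
Pasoh	27955	672	5.657
Lambir	32918	1007	5.928
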