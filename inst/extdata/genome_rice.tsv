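chrom	length_bp
Chr01	43270923
Chr02	35937250
Chr03	36413819
Chr04	35502694
Chr05	29958434
Chr06	31248787
Chr07	29697621
Chr08	28443022
Chr09	23012720
Chr10	23207287
Chr11	29021106
Chr12	27531856
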