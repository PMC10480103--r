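name	chrom	start_bp	end_bp	trait	source
PROG1	Chr07	2839476	2839979	tiller_angle	Jin et al. 2008; Tan et al. 2008
TIG1	Chr08	20931298	20932089	tiller_angle	Zhang et al. 2019
OsLG1	Chr04	33488512	33492876	spreading_panicle	Zhu et al. 2013
An-1	Chr04	16731738	16735336	awn	Luo et al. 2013
LABA1	Chr04	25959399	25963504	awn	Hua et al. 2015
SH4	Chr04	34012126	34014305	seed_shattering	Li et al. 2006
Rc	Chr07	NA	NA	red_pericarp	Sweeney et al. 2006
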