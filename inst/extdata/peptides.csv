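name,sequence,first_residue,n_terminal,c_terminal
A26-55_WT,SNKGAIIGLMVGGVVIATVIVITLVMLKKK,26,acetylated,amidated
A26-55_I45T,SNKGAIIGLMVGGVVIATVTVITLVMLKKK,26,acetylated,amidated
A28-55_WT,KKKGAIIGLMVGGVVIATVIVITLVMLKKK,26,acetylated,amidated
A28-55_I45T,KKKGAIIGLMVGGVVIATVTVITLVMLKKK,26,acetylated,amidated
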