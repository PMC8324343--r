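cell_type	gene
endothelial	Bsg
endothelial	Slc7a5
endothelial	Fn1
endothelial	Apoe
fibroblast	Atp1b2
fibroblast	Vtn
fibroblast	Fos
fibroblast	Notch3
oligodendrocyte	Mbp
oligodendrocyte	Cldn11
microglia	Lum
microglia	Dcn
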