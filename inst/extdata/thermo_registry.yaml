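# Default thermodynamic correlation set.
k1: plummer_busenberg_1982
k2: plummer_busenberg_1982
kw: millero_1995
ksp_calcite: plummer_busenberg_1982
csat_amsio2: fournier_1977
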