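site_id,temperature_C,pH,dic_mM,ca_mM,na_mM,k_mM,cl_mM,so4_mM,f_mM,sio2_mM,d13c_dic_permil
1,81.2,6.70,15.7,1.3,16.8,0.7,5.0,1.1,0.5,1.49,-4.8
2,79.6,6.80,14.9,0.7,17.5,0.7,5.3,1.2,0.5,,
3,76.7,7.07,13.7,0.7,17.5,0.7,4.9,1.1,0.5,,
4,70.7,7.45,12.8,1.0,17.3,0.8,5.1,1.1,0.5,1.36,-3.1
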