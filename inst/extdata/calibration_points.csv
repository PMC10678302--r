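therapy_name,delta_qaly,list_price,class
onasemnogene abeparvovec-xioi,20.56,2100000,rare
voretigene neparvovec,4.63,425000,rare
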