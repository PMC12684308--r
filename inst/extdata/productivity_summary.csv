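population,generation,scheme,mean_pupae,se,n_vials
BP,23,outbred,69.18,3.87,80
BP,41,outbred,90.60,4.25,81
BP,41,inbred,55.09,4.65,56
N50,13,outbred,67.18,2.96,134
N50,31,outbred,65.58,4.81,48
N50,31,inbred,53.35,5.81,40
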