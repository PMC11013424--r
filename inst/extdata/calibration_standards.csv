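compound,name,rm0,logp_lit,source
I,acetanilide,0.78,1.21,lit
II,benzoic acid,1.16,1.87,lit
III,benzophenone,2.51,3.18,lit
IV,anthracene,3.33,4.45,lit
V,"p,p'-DDT",4.69,6.38,lit
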