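group,lar_yes,lar_no,blis_yes,blis_no
White,9,24,12,21
Hispanic,6,41,25,22
AfricanAmerican,2,10,5,7
Asian,8,13,4,17
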