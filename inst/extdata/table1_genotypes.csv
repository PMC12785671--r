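# Allelic profiles (bp) of the two candidate offspring cultivars and their
# putative parents at ten SSR loci and two functional markers.
sample,population,si_group,DCA3_a,DCA3_b,DCA5_a,DCA5_b,DCA9_a,DCA9_b,DCA16_a,DCA16_b,DCA18_a,DCA18_b,EMO90_a,EMO90_b,GAPU71b_a,GAPU71b_b,GAPU101_a,GAPU101_b,GAPU103a_a,GAPU103a_b,UDO43_a,UDO43_b,OeACP1_a,OeACP1_b,OeACP2_a,OeACP2_b
Frantoio,AA,G1,237,243,198,206,182,206,150,156,177,179,188,194,124,144,183,199,162,174,176,214,333,333,389,427
Don Carlo,AA,G2,237,249,206,206,206,208,126,156,165,177,188,188,124,144,183,201,136,174,176,212,333,333,389,390
FS-17,AA,G2,231,243,206,208,206,208,150,154,173,177,190,194,124,124,199,199,172,174,212,214,320,333,427,465
Ascolana Tenera,AA,G2,231,249,206,208,194,208,126,154,173,177,188,190,124,144,199,201,136,172,176,212,320,333,390,465
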