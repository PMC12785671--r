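# Published direct-kinship dyads among the focal cultivars: triadic-ML
# relatedness point estimates and SI groups as printed (Leccino SI as
# printed per row; see table2_si_groups.csv for the text-corrected labels).
dyad,individual1,si_group1,individual2,si_group2,trioml_r
2596,Frantoio,G1,FS-17,G2,0.4605
2726,FS-17,G2,Taggiasca,G1,0.4605
2681,FS-17,G2,Leccino,G1,0.4767
521,Ascolana Tenera,G2,FS-17,G2,0.5000
2611,Frantoio,G1,Leccino,G2,0.4807
3656,Leccino,G1,Taggiasca,G1,0.4807
2305,Don Carlo,G2,Frantoio,G1,0.4758
2366,Don Carlo,G2,Taggiasca,G1,0.4758
516,Ascolana Tenera,G2,Don Carlo,G2,0.4856
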