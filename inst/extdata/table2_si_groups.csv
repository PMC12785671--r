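# Self-incompatibility group membership of the cultivars involved in the
# direct-kinship dyads.
# NOTE: the published dyad table prints Leccino inconsistently (G2 in one
# row, G1 in another); the accompanying text states unambiguously that
# Leccino and Frantoio share group G1, so Leccino is encoded here as G1.
sample,si_group
Frantoio,G1
Taggiasca,G1
Leccino,G1
FS-17,G2
Don Carlo,G2
Ascolana Tenera,G2
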