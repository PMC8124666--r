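synthetic_clone_matrix_patient8.tsv / synthetic_clone_matrix_patient14.tsv

SYNTHETIC stand-ins, not study data. They encode the published qualitative
clone-assignment pattern of the two worked-example patients (pathway 1
altered in clones 1+2 of patient 8 and clone 2 of patient 14; pathways 2
and 3 altered in clone 3 of both patients; three clones per patient) in
the package's pathway-by-clone TSV layout. The full deposited matrices
live at github.com/cbg-ethz/GeneAccord (data/clone_pws_tbl_16_WES) and can
be substituted directly via read_clone_matrix().

pathway1 = major pathway of rRNA processing in the nucleolus and cytosol
pathway2 = O-glycosylation of TSR domain-containing proteins
pathway3 = defective B3GALTL causes Peters-plus syndrome
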