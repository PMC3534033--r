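site_id	ambiguous	note
atpB.Maen.1	FALSE
atpE.Maen.2	FALSE
orf240.Maen.1	FALSE
psbD.Maen.1	FALSE
psbD.Maen.2	FALSE
rbcL.Maen.1	FALSE
rpl2.Maen.1	FALSE
rpl14.Maen.2	FALSE
rpl16.Maen.1	FALSE
rpl23.Maen.1	FALSE
rpoB.Maen.1	TRUE	located in the vicinity of rpoB.Evir.1 but relationship unknown; treated as distinct
rpoC1.Maen.5	FALSE
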