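gene	sites	egra_twintron	note
atpE	Maen.1,Egra.1	TRUE
atpF	Maen.1,Egra.2	FALSE
atpI	Maen.1,Egra.6	FALSE
chlI	Maen.1,Egra.1	FALSE
petB	Maen.1,Egra.1	TRUE
psaC	Maen.1,Egra.1	FALSE
psaC	Maen.2,Egra.2	FALSE
psbB	Maen.1,Egra.2	FALSE
psbC	Maen.1,Egra.2	TRUE
psbC	Maen.2,Egra.4,Evir.1,Egym.1	TRUE
psbK	Maen.1,Egra.2	TRUE
psbT	Maen.1,Egra.1	TRUE
rpl12	Maen.1,Egra.1,Elon.1	FALSE
rpl14	Maen.1,Egra.1,Elon.1	FALSE
rpl16	Maen.2,Egra.3,Elon.3	TRUE
rpoC1	Maen.1,Egra.1,Elon.1	TRUE
rpoC1	Maen.2,Egra.2,Elon.2	FALSE
rpoC1	Maen.3,Egra.3,Elon.3	TRUE
rpoC1	Maen.4,Egra.4,Elon.4	FALSE
rpoC1	Maen.6,Elon.7	FALSE
rpoC1	Maen.7,Egra.8,Elon.8	FALSE
rpoC1	Maen.8,Egra.9,Elon.9	FALSE
rpoC1	Maen.9,Egra.11,Elon.11	TRUE
rps2	Maen.1,Egra.1,Elon.1	FALSE
rps2	Maen.2,Egra.2,Elon.2	FALSE
rps2	Maen.3,Egra.3,Elon.3	FALSE
rps3	Maen.1,Egra.1,Elon.1	TRUE
rps3	Maen.2,Egra.2,Elon.2	FALSE
rps8	Maen.1,Egra.2,Elon.2	FALSE
rps8	Maen.2,Egra.3,Elon.3	FALSE
rps9	Maen.1,Egra.3	FALSE
rps9	Maen.2,Egra.5,Elon.4	FALSE
rps9	Maen.3,Egra.6,Elon.5	FALSE
rps11	Maen.1,Egra.1,Elon.1	FALSE
rps11	Maen.2,Egra.2,Elon.2	FALSE
rps14	Maen.1,Egra.1,Elon.1	FALSE
rps18	Maen.1,Egra.1	FALSE
rps18	Maen.2,Egra.2,Egym.1	TRUE	rps18.Egym.1 intron sequence differs and may be unrelated
rps19	Maen.1,Egra.1,Elon.1	FALSE
tufA	Maen.1,Egra.1,Elon.1	FALSE
ycf4	Maen.1,Egra.1	FALSE
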