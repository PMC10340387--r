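feature	beta	dir_surrogate	dir_rare	dir_exo	abundant
let-7d	0.479	up	up	up	TRUE
mir-181a-1	0.374	up	up	up	FALSE
mir-29c	-0.322	down	down	down	FALSE
let-7c	-0.298	down	down	up	FALSE
mir-181b-1	0.288	up	up	up	FALSE
mir-1306	0.256	up	up	up	FALSE
mir-26a-2	-0.244	down	down	down	TRUE
mir-125b-2	-0.241	down	down	up	FALSE
mir-301b	0.226	up	up	up	FALSE
mir-301a	0.215	up	up	up	FALSE
mir-877	0.215	up	up	up	FALSE
mir-660	-0.179	down	down	down	FALSE
mir-589	0.171	up	up	up	FALSE
mir-337	-0.164	down	down	down	FALSE
mir-26b	-0.162	down	down	down	TRUE
mir-502	-0.162	down	down	down	FALSE
mir-181a-2	0.141	up	up	up	TRUE
mir-654	-0.139	down	down	up	FALSE
mir-379	-0.135	down	down	down	FALSE
mir-7-3	0.13	up	up	up	TRUE
mir-218-2	-0.126	down	down	down	FALSE
mir-411	-0.0979	down	down	down	FALSE
mir-92b	0.0853	up	up	up	TRUE
mir-483	0.0848	up	up	up	FALSE
mir-362	-0.082	up	down	up	FALSE
mir-1292	0.0445	up	up	up	FALSE
mir-345	0.0433	up	up	up	FALSE
mir-1910	0.0361	up	up	up	FALSE
let-7a-3	-0.0281	down	down	down	TRUE
let-7a-1	-0.0274	down	down	down	TRUE
let-7a-2	-0.0271	down	down	down	TRUE
mir-136	-0.0218	down	down	down	FALSE
mir-1307	0.0141	up	up	up	TRUE
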