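drug	phase	n_trials
temozolomide	Phase 1	10
temozolomide	Phase 1/2	4
temozolomide	Phase 2	8
temozolomide	Phase 3	1
sirolimus	Phase 1	7
sirolimus	Phase 1/2	4
sirolimus	Phase 2	13
sirolimus	Phase 3	2
sirolimus	Phase 4	1
sirolimus	Other	1
propofol	Phase 2	1
propofol	Phase 3	2
propofol	Phase 4	7
propofol	Other	19
clarithromycin	Phase 1/2	2
clarithromycin	Phase 2	10
clarithromycin	Phase 3	3
clarithromycin	Phase 4	1
clarithromycin	Other	2
simvastatin	Phase 1	4
simvastatin	Phase 2	11
simvastatin	Phase 3	1
simvastatin	Phase 4	2
disulfiram	Phase 1	4
disulfiram	Phase 1/2	2
disulfiram	Phase 2	6
disulfiram	Phase 2/3	1
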