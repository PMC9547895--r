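sample_id	subject_id	intervention	timepoint
S0001_T0	S0001	SYNTH	baseline
S0002_T0	S0002	SYNTH	baseline
S0003_T0	S0003	SYNTH	baseline
S0004_T0	S0004	SYNTH	baseline
S0005_T0	S0005	SYNTH	baseline
S0006_T0	S0006	SYNTH	baseline
S0007_T0	S0007	SYNTH	baseline
S0008_T0	S0008	SYNTH	baseline
S0009_T0	S0009	SYNTH	baseline
S0010_T0	S0010	SYNTH	baseline
S0011_T0	S0011	SYNTH	baseline
S0012_T0	S0012	SYNTH	baseline
S0001_T1	S0001	SYNTH	after
S0002_T1	S0002	SYNTH	after
S0003_T1	S0003	SYNTH	after
S0004_T1	S0004	SYNTH	after
S0005_T1	S0005	SYNTH	after
S0006_T1	S0006	SYNTH	after
S0007_T1	S0007	SYNTH	after
S0008_T1	S0008	SYNTH	after
S0009_T1	S0009	SYNTH	after
S0010_T1	S0010	SYNTH	after
S0011_T1	S0011	SYNTH	after
S0012_T1	S0012	SYNTH	after
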