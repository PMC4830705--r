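system_id	scheme_id
2.25.1301357486	MEDC
2.25.96321772	SCTA
2.25.832123053	ICD9A
2.25.2238061593	ICD10A
2.25.3655726384	ATCA
2.25.1884955599	LABA
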