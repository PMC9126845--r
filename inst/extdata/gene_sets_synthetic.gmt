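lipid_transport	synthetic lipid transport set	GENE001	GENE002	GENE003	GENE004
glucose_response	synthetic glucose response set	GENE005	GENE006	GENE007
muscle_development	synthetic muscle set	GENE008	GENE009	GENE010	GENE011	GENE012
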