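module_a	synthetic example set	g001	g002	g003	g004	g005
module_b	synthetic example set	g006	g007	g008	g009	g010
mixed	synthetic example set	g001	g004	g007	g010	g012
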