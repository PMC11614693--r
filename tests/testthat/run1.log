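[2026-09-26 09:31:46] cps fit (cpstraj 0.1.0) seed=1
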