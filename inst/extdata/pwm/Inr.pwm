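>Inr synthetic example PWM (TTCAATTC consensus, spans the TSS)
A [ 10 10 10 70 70 10 10 10 ]
C [ 10 10 70 10 10 10 10 70 ]
G [ 10 10 10 10 10 10 10 10 ]
T [ 70 70 10 10 10 70 70 10 ]
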