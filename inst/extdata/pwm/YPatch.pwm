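>YPatch synthetic example PWM (CTTCTTCC consensus, pyrimidine-rich)
A [  5  5  5  5  5  5  5  5 ]
C [ 70 20 20 70 20 20 70 70 ]
G [  5  5  5  5  5  5  5  5 ]
T [ 20 70 70 20 70 70 20 20 ]
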