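# synthetic example Y patch (pyrimidine patch) octamer list
CTTCTTCC
CTCTTCTC
TTCTTCTC
TCTTCTCC
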