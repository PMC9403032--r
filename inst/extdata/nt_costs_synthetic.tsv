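nt	cost
A	50
C	52
G	54
T	48
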