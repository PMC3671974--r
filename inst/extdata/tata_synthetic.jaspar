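>TATA_SYN synthetic consensus-derived TATA-box position count matrix
A  [   0   0 100   0 100 100 100 100   0   0  20  20  20 ]
C  [   0   0   0   0   0   0   0   0   0   0  20  20  20 ]
G  [ 100   0   0   0   0   0   0   0 100 100  40  40  40 ]
T  [   0 100   0 100   0   0   0   0   0   0  20  20  20 ]
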