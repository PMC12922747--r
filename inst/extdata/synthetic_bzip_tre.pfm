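>SYN0001.1 synthetic_bZIP_TRE
A [  2   3  90   3   2   3  88 ]
C [  3   2   3  90   3  91   4 ]
G [  4  92   4   3   4   3   4 ]
T [ 91   3   3   4  91   3   4 ]
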