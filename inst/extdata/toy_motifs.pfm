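>TOY0001 ERF
A [  2  1 95  1  1  2 90  3 ]
C [  3 95  1  2 95  2  4  2 ]
G [ 92  2  2 95  2  2  3  3 ]
T [  3  2  2  2  2 94  3 92 ]
>TOY0002 WRKY
A [  1 90  2  2  1  3  2 ]
C [  2  3  1  2  2 92  3 ]
G [ 94  3 94  2  3  2  2 ]
T [  3  4  3 94 94  3 93 ]
>TOY0003 bHLH
A [  2  1 92  2  2  1 ]
C [ 93  2  2  1 93  3 ]
G [  2 94  3  2  2  2 ]
T [  3  3  3 95  3 94 ]
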