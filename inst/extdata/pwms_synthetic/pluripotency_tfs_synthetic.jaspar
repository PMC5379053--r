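>SYN0001.1 Esrrb
A [  4  3 85 90  2  3  5 10 70 ]
C [  8 87  5  4  3  2  5 80 10 ]
G [  4  5  5  3 90 92  5  5 10 ]
T [ 84  5  5  3  5  3 85  5 10 ]
>SYN0002.1 Klf4
A [  5  3  2  5  5  4  3  5 15 ]
C [  5  4  3  5 10  3  4  5 15 ]
G [ 85 90 92 85  5 90 90 85 55 ]
T [  5  3  3  5 80  3  3  5 15 ]
>SYN0003.1 Sox2
A [  5 85  5  4  5  5 10 ]
C [ 80  5  5  3  5  5 10 ]
G [  5  5  5  3 85  5 10 ]
T [ 10  5 85 90  5 85 70 ]
>SYN0004.1 Oct4
A [ 85  5  5  5 88 90 85  5 ]
C [  5  5  5 82  4  4  5  5 ]
G [  5  5 85  8  4  3  5  5 ]
T [  5 85  5  5  4  3  5 85 ]
>SYN0005.1 Nanog
A [  5 85 86  5  5  8 ]
C [  5  5  4  5  5  8 ]
G [  5  5  5  5 85 76 ]
T [ 85  5  5 85  5  8 ]
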