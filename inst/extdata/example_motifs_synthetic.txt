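>EXAMPLE_A
0.05000000000000001	0.84999999999999998	0.05000000000000001	0.05000000000000001
0.05000000000000001	0.84999999999999998	0.05000000000000001	0.05000000000000001
0.05000000000000001	0.05000000000000001	0.05000000000000001	0.84999999999999998
0.84999999999999998	0.05000000000000001	0.05000000000000001	0.05000000000000001
0.05000000000000001	0.05000000000000001	0.05000000000000001	0.84999999999999998
0.84999999999999998	0.05000000000000001	0.05000000000000001	0.05000000000000001
0.84999999999999998	0.05000000000000001	0.05000000000000001	0.05000000000000001
0.05000000000000001	0.05000000000000001	0.05000000000000001	0.84999999999999998
>EXAMPLE_B
0.05000000000000001	0.84999999999999998	0.05000000000000001	0.05000000000000001
0.84999999999999998	0.05000000000000001	0.05000000000000001	0.05000000000000001
0.05000000000000001	0.05000000000000001	0.05000000000000001	0.84999999999999998
0.05000000000000001	0.84999999999999998	0.05000000000000001	0.05000000000000001
0.05000000000000001	0.84999999999999998	0.05000000000000001	0.05000000000000001
0.05000000000000001	0.05000000000000001	0.05000000000000001	0.84999999999999998
0.05000000000000001	0.05000000000000001	0.05000000000000001	0.84999999999999998
0.05000000000000001	0.05000000000000001	0.84999999999999998	0.05000000000000001
>EXAMPLE_C
0.05000000000000001	0.84999999999999998	0.05000000000000001	0.05000000000000001
0.05000000000000001	0.05000000000000001	0.05000000000000001	0.84999999999999998
0.05000000000000001	0.84999999999999998	0.05000000000000001	0.05000000000000001
0.05000000000000001	0.05000000000000001	0.05000000000000001	0.84999999999999998
0.84999999999999998	0.05000000000000001	0.05000000000000001	0.05000000000000001
0.05000000000000001	0.84999999999999998	0.05000000000000001	0.05000000000000001
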