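>CEBPA_synthetic (synthetic example PFM for tests and demos; not a database motif)
A  [  12   5  88   2   6   4  90  85  10  30 ]
C  [  10   4   2   3  85   4   2   5  15  25 ]
G  [  15   6   5  90   4   3   5   4  60  25 ]
T  [  63  85   5   5   5  89   3   6  15  20 ]
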