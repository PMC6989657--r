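theta,removed_types,remaining_types
1,20293,28555
5,33102,15746
10,37205,11643
25,41270,7578
50,43632,5216
100,45579,3269
200,46859,1989
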