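# toy two-camp signed network (SNAP soc-sign dialect)
# camps {0,2,4} and {1,3,5}: positive within, negative across
0 2 1
2 4 1
0 4 1
1 3 1
3 5 1
1 5 1
0 1 -1
2 3 -1
4 5 -1
0 3 -1
3 0 -1
2 2 1
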