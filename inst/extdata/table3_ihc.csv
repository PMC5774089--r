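# Per-animal terminal immunohistochemistry (day 7, explanted tumors).
# cd31: positively stained microvessels in ten random fields at 200x (microvascular density).
# ki67: positively stained nuclei in ten random fields at 200x (proliferation).
# group: T = therapy, C = control.
animal_id,group,cd31,ki67
1,T,166,4433
2,T,83,5831
3,T,212,3189
4,T,129,2649
5,T,222,2832
6,T,182,3820
7,T,79,4033
8,T,105,2912
9,T,100,2227
10,T,151,4306
11,T,179,4210
12,T,151,4177
13,C,271,6801
14,C,336,6349
15,C,447,6489
16,C,191,3799
17,C,307,4562
18,C,358,4582
19,C,261,3379
20,C,284,5718
21,C,132,6824
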