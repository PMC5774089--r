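# Per-animal 18F-FDG-PET semiquantification: tumor-to-liver ratio (TTL, dimensionless)
# and metabolic tumor volume (MTV, mm^3) at baseline (day 0) and follow-up (day 7).
# group: T = therapy (dabrafenib + ribociclib), C = control (placebo). n = 12 T, 9 C.
# *_delta_printed columns transcribe the published delta column verbatim and are kept
# for cross-checking only; analyses always recompute delta = followup - baseline.
# Known transcription anomaly: animal 5 ttl_delta_printed is 0.06 in print while
# followup - baseline = -0.06; the recomputed value reproduces the published group mean.
animal_id,group,ttl_baseline,ttl_followup,ttl_delta_printed,mtv_baseline_mm3,mtv_followup_mm3,mtv_delta_printed_mm3
1,T,5.63,4.83,-0.79,296.0,311.4,15.4
2,T,4.80,3.13,-1.67,86.8,50.4,-36.4
3,T,5.90,5.26,-0.64,56.1,162.7,106.6
4,T,3.72,2.65,-1.07,155.9,417.9,262.0
5,T,3.94,3.88,0.06,142.5,433.7,291.2
6,T,4.57,3.02,-1.55,230.8,185.2,-45.6
7,T,4.61,2.90,-1.71,112.8,78.2,-34.6
8,T,3.69,2.40,-1.29,162.7,118.0,-44.7
9,T,3.11,2.52,-0.59,332.0,392.0,60.0
10,T,3.59,2.46,-1.13,171.3,161.7,-9.6
11,T,4.14,2.93,-1.21,120.0,80.6,-39.4
12,T,2.57,2.29,-0.28,66.2,147.8,81.6
13,C,4.34,4.06,-0.28,96.9,344.0,247.1
14,C,3.07,5.13,2.06,519.1,1192.3,673.2
15,C,5.62,5.50,-0.12,213.0,616.1,403.1
16,C,2.88,3.95,1.07,140.1,329.1,189.0
17,C,4.02,4.13,0.11,222.6,597.8,375.2
18,C,3.31,5.25,1.94,165.1,511.0,345.9
19,C,3.50,5.45,1.95,115.6,421.3,305.7
20,C,2.71,4.73,2.02,392.5,866.5,474.0
21,C,3.81,2.72,-1.09,96.0,283.1,187.1
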