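# Per-animal DW-MRI apparent diffusion coefficient (ADC) and T2w morphological tumor
# volume at baseline (day 0) and follow-up (day 7).
# group: T = therapy, C = control.
# ADC columns are stored in canonical units of mm^2/s; the published table prints
# ADC on the x10^-3 mm^2/s scale, so printed 0.84 is stored as 0.00084.
# *_delta_printed columns transcribe the published delta column (same unit convention)
# and are kept for cross-checking only; analyses recompute delta = followup - baseline.
animal_id,group,adc_baseline_mm2s,adc_followup_mm2s,adc_delta_printed_mm2s,vol_baseline_mm3,vol_followup_mm3,vol_delta_printed_mm3
1,T,0.00084,0.00084,0.00000,163.0,166.3,3.3
2,T,0.00088,0.00116,0.00028,25.7,33.5,7.8
3,T,0.00074,0.00072,-0.00002,19.1,99.5,80.4
4,T,0.00077,0.00086,0.00009,188.8,255.5,66.7
5,T,0.00087,0.00082,-0.00005,88.5,281.1,192.6
6,T,0.00062,0.00084,0.00022,154.9,107.7,-47.2
7,T,0.00079,0.00107,0.00028,67.2,48.3,-18.9
8,T,0.00071,0.00087,0.00016,38.7,50.8,12.1
9,T,0.00066,0.00083,0.00017,232.5,264.1,31.6
10,T,0.00073,0.00081,0.00008,62.0,123.0,61.0
11,T,0.00076,0.00107,0.00031,48.9,31.9,-17.0
12,T,0.00097,0.00085,-0.00012,45.6,107.9,62.3
13,C,0.00085,0.00077,-0.00008,119.0,356.0,237.0
14,C,0.00070,0.00063,-0.00007,320.6,777.6,457.0
15,C,0.00086,0.00069,-0.00017,103.1,379.7,276.6
16,C,0.00096,0.00076,-0.00020,81.5,212.9,131.4
17,C,0.00078,0.00063,-0.00015,138.0,371.4,233.4
18,C,0.00073,0.00061,-0.00012,109.0,292.9,183.9
19,C,0.00087,0.00071,-0.00016,72.7,301.7,229.0
20,C,0.00061,0.00061,0.00000,232.7,541.0,308.3
21,C,0.00079,0.00069,-0.00010,31.8,203.5,171.7
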