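sow_id,ca_pct,da_pct
03,44.9,95.0
04,50.7,91.7
05,58.1,94.1
06,75.2,95.9
07,52.2,96.4
08,66.6,96.8
09,65.7,94.3
10,66.2,81.2
15,61.7,84.4
16,42.3,90.3
17,52.5,89.9
18,57.9,92.1
19,69.0,95.2
20,93.6,98.3
21,73.9,99.6
22,71.0,93.1
25,58.8,99.3
26,56.3,83.6
27,58.6,87.1
28,66.1,99.4
29,82.3,88.0
30,66.2,98.4
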