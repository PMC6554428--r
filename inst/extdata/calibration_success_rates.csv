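subject,ssvep_pct,mi_csp_pct,mi_cicsp_pct,blink_pct,entire_task_pct
1,78.44,82.61,84.43,100,87.62
2,62.19,74.72,78.82,97.92,79.64
3,99.38,51.54,60.14,100,86.51
4,50.63,41.62,49.63,100,66.75
5,97.76,86.94,88.76,97.92,94.81
6,97.06,91.51,93.70,100,96.92
7,97.62,92.04,91.63,100,96.42
8,87.05,85.99,87.97,95.83,90.28
9,80.80,86.20,88.95,100,89.92
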