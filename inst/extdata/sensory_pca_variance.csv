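pc,eigenvalue,variance_pct,cumulative_pct
PC1,23.4764,40.19,40.19
PC2,12.2912,21.04,61.24
PC3,12.1340,20.77,82.01
PC4,6.1666,10.56,92.57
PC5,2.6346,4.51,97.08
PC6,1.7059,2.92,100.00
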