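population,mouse,int_fr_hand,int_fr_hand_cortex,pct_printed
S1 all,1,271.1,225.7,83.3
S1 all,2,155.2,76,49.0
S1 all,3,94.1,75.1,79.8
S1 all,4,228.4,165.2,72.3
S1 PV,1,355.6,317.6,89.3
S1 PV,2,183.4,100.7,54.9
S1 PV,3,111.4,96,86.2
S1 PV,4,308.9,222.2,71.9
S1 non-PV,1,216.4,166.3,76.8
S1 non-PV,2,111.7,38,34.0
S1 non-PV,3,66.2,41.5,62.7
S1 non-PV,4,151.6,110.8,73.2
M1 all,1,81.9,71.4,87.2
M1 all,2,46.1,31.2,67.7
M1 all,3,79.8,63.9,80.1
M1 all,4,47.2,33.6,71.2
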