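# ace-band-table v1 — 22-channel allocation of 125 Hz FFT bins (128-pt FFT @ 16 kHz)
band,bin_lo,bin_hi,lower_hz,upper_hz,center_hz
1,2,2,187.5,312.5,250
2,3,3,312.5,437.5,375
3,4,4,437.5,562.5,500
4,5,5,562.5,687.5,625
5,6,6,687.5,812.5,750
6,7,7,812.5,937.5,875
7,8,8,937.5,1062.5,1000
8,9,9,1062.5,1187.5,1125
9,10,10,1187.5,1312.5,1250
10,11,12,1312.5,1562.5,1437.5
11,13,14,1562.5,1812.5,1687.5
12,15,16,1812.5,2062.5,1937.5
13,17,18,2062.5,2312.5,2187.5
14,19,21,2312.5,2687.5,2500
15,22,24,2687.5,3062.5,2875
16,25,28,3062.5,3562.5,3312.5
17,29,32,3562.5,4062.5,3812.5
18,33,37,4062.5,4687.5,4375
19,38,42,4687.5,5312.5,5000
20,43,48,5312.5,6062.5,5687.5
21,49,55,6062.5,6937.5,6500
22,56,63,6937.5,7937.5,7437.5
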