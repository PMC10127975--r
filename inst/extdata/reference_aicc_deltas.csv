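patient,exponential,fractional_exponential,logistic,fractional_logistic,exponential_linear,fractional_exponential_linear
1,0,5.60,1.43,7.03,5.60,14.93
2,0.84,2.03,0,1.70,4.98,10.66
3,3.79,3.95,0,5.60,1.73,10.99
4,0,7.00,0.83,7.83,7.00,21.00
5,0,5.60,1.33,6.93,5.60,14.93
6,0,5.60,1.86,7.46,5.60,14.93
7,0,5.60,4.42,10.02,5.60,14.93
8,0,5.60,1.54,7.14,5.60,14.93
9,0,7.00,4.41,11.41,7.00,21.00
10,0,4.80,2.07,6.87,4.80,12.00
11,0,5.60,0.15,5.75,5.51,14.84
12,0,5.60,0.37,5.97,5.60,14.93
13,0,5.60,0.76,6.36,5.60,14.93
14,0.50,0,14.07,19.67,2.82,9.33
15,0,5.60,3.91,9.51,5.65,14.98
16,0,5.60,2.12,7.72,5.60,14.93
17,0.14,5.74,0,5.60,5.46,14.80
18,0,5.60,0.54,6.14,5.60,14.93
19,0,4.80,1.98,6.78,4.80,12.00
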