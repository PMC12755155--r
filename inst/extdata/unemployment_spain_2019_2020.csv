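age_group,gender,2019,2020
16-19,f,48.47,60.97
20-24,f,31.65,36.22
25-29,f,19.10,23.69
30-34,f,16.34,18.67
35-39,f,13.46,16.68
40-44,f,13.97,14.61
45-49,f,13.92,14.79
50-54,f,14.85,14.22
55-59,f,13.82,14.26
16-19,m,42.82,50.11
20-24,m,28.18,34.23
25-29,m,18.87,22.16
30-34,m,11.66,15.08
35-39,m,9.68,11.79
40-44,m,9.22,9.87
45-49,m,9.48,10.24
50-54,m,10.44,10.63
55-59,m,11.68,11.01
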