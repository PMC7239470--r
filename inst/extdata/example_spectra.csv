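wl,m01_cold_r1,m01_cold_r2,m01_warm_r1,m01_warm_r2,f01_cold_r1,f01_warm_r1
300,4.686,4.001,4.002,4.464,4.23,4.229
305,3.641,4.009,4.223,3.889,3.816,4.168
310,3.792,3.882,4.313,4.588,4.046,4.48
315,3.876,3.762,3.904,3.817,3.822,3.97
320,3.709,3.906,4.097,3.977,3.712,3.565
325,3.716,3.896,4.206,3.452,3.825,3.923
330,4.224,3.909,4.096,4.242,4.197,3.39
335,3.965,3.464,3.426,3.557,3.913,4.176
340,4.046,4.176,3.3,3.109,4.271,4.048
345,4.657,4.491,4.148,3.601,4.06,4.034
350,4.107,3.806,4.359,3.925,3.985,4.172
355,4.815,4.186,3.621,3.894,3.728,3.711
360,4.684,4.071,4.201,3.835,3.657,4.096
365,4.097,4.254,4.105,3.831,4.297,3.95
370,4.569,3.828,4.267,4.573,4.034,3.729
375,4.14,4.335,4.478,4.07,4.345,3.451
380,3.732,3.538,4.175,4.17,3.727,4.21
385,3.908,3.869,4.03,3.969,3.669,3.984
390,3.999,3.955,4.985,3.843,3.51,4.498
395,4.296,4.156,5.199,5.297,3.515,3.792
400,4.252,4.176,5.092,5.023,3.749,4.403
405,4.212,3.976,5.049,5.318,4.328,4.208
410,4.392,3.648,5.736,5.644,4.371,3.95
415,3.584,4.093,6.086,5.936,4.052,4.268
420,4.382,3.519,7.429,6.947,4.036,4.751
425,4.055,4.298,8.347,7.707,4.167,4.774
430,4.226,4.307,9.056,9.684,4.147,4.77
435,4.178,4.253,11.081,11.114,3.979,5.205
440,3.707,4.038,12.713,12.857,3.595,5.804
445,3.92,3.875,15.971,14.887,4.24,6.543
450,3.744,4.144,18.123,17.069,3.904,6.537
455,4.225,4.204,20.708,20.106,3.893,8.141
460,4.049,4.201,23.986,23.612,3.847,8.767
465,4.004,3.763,27.151,26.004,3.438,10.684
470,3.919,4.512,29.728,28.73,3.717,11.143
475,3.904,3.707,32.709,31.509,4.686,12.862
480,4.414,4.456,34.931,33.704,4.067,15.108
485,3.846,4.489,37.195,35.749,3.319,16.343
490,4.228,4.387,38.914,36.56,4.002,17.59
495,4.497,3.974,39.202,36.504,4.049,19.217
500,4.952,5.113,38.864,36.702,4.261,19.867
505,4.629,5.124,38.278,36.191,3.897,20.784
510,5.089,5.231,37.032,34.647,4.205,21.477
515,5.218,5.981,34.312,32.958,4.365,21.915
520,6.049,6.829,32.021,30.725,4.887,21.735
525,6.733,7.273,29.533,27.915,4.641,21.024
530,8.088,8.038,26.022,25.451,4.044,21.225
535,8.834,8.653,23.785,22.105,5.012,19.31
540,9.801,10.617,20.463,20.01,5.111,18.16
545,11.285,11.484,17.185,16.57,5.196,17.104
550,12.255,13.358,14.928,14.488,5.917,14.952
555,13.711,14.883,12.703,11.809,5.833,13.344
560,15.204,16.243,10.668,10.548,6.83,11.915
565,16.927,17.917,9.766,8.942,7.348,10.928
570,17.831,18.661,7.959,7.497,8.193,9.398
575,18.774,20.131,6.987,6.136,8.089,8.374
580,18.936,21.121,5.839,5.835,8.87,7.398
585,19.998,21.468,5.415,5.621,10.675,6.733
590,20.14,21.892,5.057,4.974,10.772,6.258
595,19.692,21.009,4.438,4.796,11.433,5.523
600,19.555,20.71,4.919,4.49,11.633,4.746
605,18.881,20.251,4.678,4.394,12.161,4.76
610,18.078,19.251,4.348,4.155,11.63,4.763
615,17.051,18.146,4.934,5.076,12.685,5.154
620,15.773,16.694,4.664,4.588,12.064,4.737
625,14.832,15.142,4.6,4.543,12.196,4.886
630,13.601,14.297,4.948,5.401,11.832,5.004
635,12.692,13.104,4.79,5.651,11.855,5.383
640,11.842,11.675,5.996,6.081,11.224,5.296
645,10.952,11.072,5.938,6.624,11.031,6.672
650,10.311,10.855,6.507,5.697,11.011,6.547
655,9.488,9.76,6.836,7.112,10.786,7.046
660,9.284,9.61,7.761,7.658,10.616,7.781
665,9.006,9.621,7.214,7.774,9.875,7.582
670,8.639,9.002,7.952,7.6,9.771,7.941
675,8.646,8.645,8.213,8.099,10.061,8.199
680,8.724,9.4,8.404,7.964,9.52,9.104
685,8.793,9.365,8.428,8.231,9.816,8.529
690,8.927,8.967,8.553,8.478,9.156,8.725
695,9.667,9.061,8.809,9.442,9.618,8.682
700,9.045,8.981,8.536,8.854,9.599,9.081
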