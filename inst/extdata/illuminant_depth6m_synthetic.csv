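wavelength_nm,value
300,0.03589
305,0.04165
310,0.04828
315,0.05591
320,0.06466
325,0.0747
330,0.08619
335,0.09934
340,0.11436
345,0.1315
350,0.15103
355,0.17326
360,0.19854
365,0.22724
370,0.25979
375,0.29666
380,0.33836
385,0.38548
390,0.43865
395,0.49859
400,0.56605
405,0.58665
410,0.60729
415,0.62793
420,0.64852
425,0.66902
430,0.68935
435,0.70949
440,0.72937
445,0.74893
450,0.76813
455,0.78691
460,0.80521
465,0.82299
470,0.84018
475,0.85674
480,0.87261
485,0.88775
490,0.9021
495,0.91562
500,0.92827
505,0.94001
510,0.95079
515,0.96058
520,0.96934
525,0.97706
530,0.98369
535,0.98922
540,0.99363
545,0.9969
550,0.99903
555,1
560,0.99981
565,0.99847
570,0.99597
575,0.99232
580,0.98754
585,0.87065
590,0.7667
595,0.67438
600,0.59249
605,0.51994
610,0.45574
615,0.39901
620,0.34894
625,0.30479
630,0.26593
635,0.23175
640,0.20173
645,0.17539
650,0.15232
655,0.13213
660,0.11448
665,0.09907
670,0.08564
675,0.07394
680,0.06377
685,0.05493
690,0.04727
695,0.04062
700,0.03487
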