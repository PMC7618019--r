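# Molar extinction coefficients of oxy- and deoxyhemoglobin (L mol-1 cm-1),
# approximate transcription of the standard compiled literature curves,
# tabulated at 5 nm. Lookups interpolate linearly and never extrapolate.
wavelength_nm	eps_hbo2	eps_hb
445	73000	128000
450	62816	103292
455	52500	84000
460	44480	68000
465	38500	55500
470	33209	45500
475	29600	38500
480	26629	33000
485	24400	29000
490	23100	26100
495	21800	23400
500	20932	20862
505	20300	23200
510	20035	25773
515	20900	28300
520	24202	31000
525	31000	34500
530	39956	39036
535	47500	43200
540	53236	46592
545	52000	50500
550	43016	53412
555	36500	55540
560	32600	53788
565	36000	51000
570	44496	45072
575	54500	39500
580	50104	37020
585	31500	33200
590	14400	28000
595	7000	21500
600	3200	14677
605	2000	11500
610	1506	9444
615	1166	8000
620	942	6935
625	740	6000
630	610	5149
635	540	4700
640	442	4345
645	400	4050
650	368	3750
655	340	3500
660	320	3227
665	305	3000
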