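# Cholesterol 1H-NMR reference resonances (HMDB entry 2491, 400 MHz).
# 14 characteristic peaks spanning 0.678-5.356 ppm. Rows flagged
# provenance=printed carry positions/intensities stated in the source
# assignment table; provenance=placeholder rows are synthetic stand-ins
# chosen inside the stated region for that peak group (the full appendix
# table is not publicly printed) and are flagged so matching results can be
# interpreted accordingly. The olefinic resonance is variously quoted as
# 5.348, 5.35 and 5.356 ppm; 5.35 is stored.
peak_id,ppm,intensity,provenance,assignment
1,0.678,420,printed,"C18 angular methyl"
2,0.778,180,placeholder,"side-chain methyl (0.7-1.0 ppm group)"
3,0.876,540,printed,"C19/C21 methyl"
4,0.936,310,placeholder,"side-chain methyl (0.7-1.0 ppm group)"
5,1.007,1000,printed,"overlapping methyl/methylene envelope, steroid core"
6,1.15,260,placeholder,"methylene (1.1-1.5 ppm group)"
7,1.3,340,placeholder,"methylene (1.1-1.5 ppm group)"
8,1.48,290,placeholder,"methylene (1.1-1.5 ppm group)"
9,1.854,330,printed,"methylene adjacent to ring junction"
10,1.98,240,placeholder,"proton adjacent to functional group (1.8-2.3 ppm)"
11,2.12,200,placeholder,"proton adjacent to functional group (1.8-2.3 ppm)"
12,2.28,170,placeholder,"proton adjacent to functional group (1.8-2.3 ppm)"
13,3.5,120,printed,"C3 hydroxyl-bearing methine"
14,5.35,90,printed,"olefinic proton, C5-C6 double bond"
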