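protein1 protein2 neighborhood fusion cooccurence coexpression experimental database textmining combined_score
9606.ENSP00000001001 9606.ENSP00000001003 0 0 0 120 845 900 400 980
9606.ENSP00000001003 9606.ENSP00000001001 0 0 0 120 845 900 400 980
9606.ENSP00000001001 9606.ENSP00000001008 0 0 0 60 0 0 250 310
9606.ENSP00000001008 9606.ENSP00000001001 0 0 0 60 0 0 250 310
9606.ENSP00000001002 9606.ENSP00000001008 0 0 0 45 0 0 180 220
9606.ENSP00000001008 9606.ENSP00000001002 0 0 0 45 0 0 180 220
9606.ENSP00000001003 9606.ENSP00000001004 0 0 0 200 910 900 600 995
9606.ENSP00000001004 9606.ENSP00000001003 0 0 0 200 910 900 600 995
9606.ENSP00000001003 9606.ENSP00000001010 0 0 0 80 420 500 300 760
9606.ENSP00000001010 9606.ENSP00000001003 0 0 0 80 420 500 300 760
9606.ENSP00000001005 9606.ENSP00000001011 0 0 0 30 150 0 200 330
9606.ENSP00000001011 9606.ENSP00000001005 0 0 0 30 150 0 200 330
9606.ENSP00000001006 9606.ENSP00000001012 0 0 0 25 95 0 150 240
9606.ENSP00000001012 9606.ENSP00000001006 0 0 0 25 95 0 150 240
9606.ENSP00000001009 9606.ENSP00000001010 0 0 0 110 705 800 350 930
9606.ENSP00000001010 9606.ENSP00000001009 0 0 0 110 705 800 350 930
9606.ENSP00000001002 9606.ENSP00000001007 0 0 0 10 0 0 120 150
9606.ENSP00000001007 9606.ENSP00000001002 0 0 0 10 0 0 120 150
9606.ENSP00000001001 9606.ENSP00000009999 0 0 0 90 600 0 300 720
9606.ENSP00000009999 9606.ENSP00000001001 0 0 0 90 600 0 300 720
9606.ENSP00000008888 9606.ENSP00000009999 0 0 0 40 300 0 200 420
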