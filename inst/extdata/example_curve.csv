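time_ms,volume_ml
0,107.21128753414399
31.333333333333332,106.63059054858117
62.666666666666664,106.68233758662136
94,104.09419704237425
125.33333333333333,96.61290452157309
156.66666666666666,84.09294460580699
188,69.24364340151789
219.33333333333334,53.76183042245972
250.66666666666666,42.884432078458374
282,35.84440810729004
313.3333333333333,34.282044932898046
344.6666666666667,34.48599361781033
376,33.57979691829636
407.3333333333333,35.243795901981365
438.6666666666667,38.569347384534666
470,44.28032356157493
501.3333333333333,51.28887923105432
532.6666666666666,58.746069107249824
564,66.68584253918785
595.3333333333334,74.30273124585727
626.6666666666666,78.22912435213388
658,80.04385787701601
689.3333333333334,81.17278920257561
720.6666666666666,81.61770078661286
752,82.68332054756995
783.3333333333334,85.8161655987455
814.6666666666666,92.65279173697417
846,99.51318157307526
877.3333333333334,105.16254737061456
908.6666666666666,106.52984260737318
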