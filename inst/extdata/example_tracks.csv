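time_ms,distance_mm,site
0,94.99624862382132,septal
31.333333333333332,94.8389256726335,septal
62.666666666666664,94.76516883975641,septal
94,94.14542543930509,septal
125.33333333333333,92.5959620377316,septal
156.66666666666666,90.65503491473244,septal
188,88.46386729849513,septal
219.33333333333334,86.3437971547352,septal
250.66666666666666,84.7530945314863,septal
282,83.80192631471105,septal
313.3333333333333,83.92183414663869,septal
344.6666666666667,83.63361107319129,septal
376,83.82733169510857,septal
407.3333333333333,84.64043366727755,septal
438.6666666666667,85.99198272031374,septal
470,88.1393608685571,septal
501.3333333333333,90.24206697111751,septal
532.6666666666666,91.75139749955393,septal
564,93.07364403542324,septal
595.3333333333334,93.41448735381535,septal
626.6666666666666,93.51409577720418,septal
658,93.60342484049279,septal
689.3333333333334,93.49366967655989,septal
720.6666666666666,93.5289905969591,septal
752,93.58827958905249,septal
783.3333333333334,93.50067116632471,septal
814.6666666666666,93.44031522084647,septal
846,93.97197490404787,septal
877.3333333333334,94.5423815350526,septal
908.6666666666666,94.88965960618042,septal
0,95.06539182563938,lateral
31.333333333333332,94.99767181789345,lateral
62.666666666666664,94.59688929552557,lateral
94,93.93115736830492,lateral
125.33333333333333,92.16986805714511,lateral
156.66666666666666,89.80970888067971,lateral
188,87.38976869825747,lateral
219.33333333333334,84.85065707821376,lateral
250.66666666666666,82.91665135869069,lateral
282,82.02202602070547,lateral
313.3333333333333,81.84761652735344,lateral
344.6666666666667,81.76597096478397,lateral
376,81.88039562172935,lateral
407.3333333333333,82.66437772869187,lateral
438.6666666666667,84.34519199860053,lateral
470,86.73484196388277,lateral
501.3333333333333,89.4182420609122,lateral
532.6666666666666,91.24799692214448,lateral
564,93.02289511129929,lateral
595.3333333333334,93.34698371728234,lateral
626.6666666666666,93.28358794031891,lateral
658,93.31944248884568,lateral
689.3333333333334,93.1850590813503,lateral
720.6666666666666,93.21226507354466,lateral
752,93.2745936130858,lateral
783.3333333333334,93.05217960925435,lateral
814.6666666666666,93.28390783156522,lateral
846,93.92451155906609,lateral
877.3333333333334,94.69610013479229,lateral
908.6666666666666,94.98004447355942,lateral
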