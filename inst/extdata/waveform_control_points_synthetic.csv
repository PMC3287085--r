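"t_seconds","velocity_m_per_s"
0,0.00280054
0.025,0.00280011
0.05,0.00280002
0.075,0.00280001
0.1,0.00280003
0.125,0.00280023
0.15,0.0028014
0.175,0.00280724
0.2,0.00283153
0.225,0.0029154
0.25,0.00315532
0.275,0.00372018
0.3,0.00480443
0.325,0.00647258
0.35,0.00846
0.375,0.01013716
0.4,0.01080054
0.425,0.01013933
0.45,0.00846848
0.475,0.00650043
0.5,0.00488502
0.525,0.00392597
0.55,0.00361907
0.575,0.00383769
0.6,0.0044502
0.625,0.00531429
0.65,0.00622812
0.675,0.00693365
0.7,0.00720003
0.725,0.00693342
0.75,0.00622672
0.775,0.00530704
0.8,0.00441867
0.825,0.00372229
0.85,0.00326376
0.875,0.00300579
0.9,0.00288059
0.925,0.00282785
0.95,0.00280849
0.975,0.00280229
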