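label,x1,n1,x2,n2,p1,p2,ci_lo,ci_hi,p_value
Tumor site: Anterior,23,56,22,71,0.411,0.310,-0.083,0.285,0.321
Tumor site: Lateral,27,56,34,71,0.482,0.479,-0.175,0.182,0.999
Tumor site: Posterior,2,56,13,71,0.036,0.183,-0.266,-0.029,0.023
Tumor site: Central,3,56,2,71,0.054,0.028,-0.061,0.112,0.786
Tumor site: Absent,1,56,0,71,0.018,0.000,-0.033,0.069,0.905
Focality: Unifocal,43,56,63,71,0.768,0.887,-0.268,0.029,0.119
Focality: Multifocal,13,56,8,71,0.232,0.113,-0.029,0.268,0.119
Vulvar surgery: Partial,42,56,24,71,0.750,0.338,0.238,0.586,<0.001
Vulvar surgery: Radical,32,56,29,71,0.571,0.408,-0.026,0.352,0.099
Side of surgery: Monolateral,4,56,12,71,0.071,0.169,-0.224,0.029,0.169
Side of surgery: Bilateral,52,56,59,71,0.929,0.831,-0.029,0.224,0.169
Histotype: Squamous,46,56,63,71,0.821,0.887,-0.206,0.074,0.423
Histotype: Paget,4,56,5,71,0.071,0.070,-0.090,0.092,0.999
Histotype: Melanoma,3,56,2,71,0.054,0.028,-0.061,0.112,0.786
Histotype: Basocellular,1,56,0,71,0.018,0.000,-0.033,0.069,0.905
Histotype: Adenocarcinoma,0,56,1,71,0.000,0.014,-0.056,0.027,0.999
Histotype: Sarcoma,1,56,0,71,0.018,0.000,-0.033,0.069,0.905
Maximum tumor diameter: <20 mm,6,56,22,71,0.107,0.310,-0.353,-0.052,0.012
Maximum tumor diameter: 20-40 mm,21,56,31,71,0.375,0.437,-0.249,0.126,0.604
Maximum tumor diameter: >40 mm,27,56,15,71,0.482,0.211,0.093,0.449,0.002
Grading: G1,6,56,14,71,0.107,0.197,-0.229,0.049,0.255
Grading: G2,29,56,34,71,0.518,0.479,-0.152,0.230,0.797
Grading: G3,12,56,7,71,0.214,0.099,-0.028,0.260,0.118
Depth of invasion: <5 mm,12,56,20,71,0.214,0.282,-0.233,0.099,0.507
Depth of invasion: >=5 mm,31,56,23,71,0.554,0.324,0.044,0.415,0.016
Lymphovascular invasion: Absent,9,56,22,71,0.161,0.310,-0.309,0.011,0.083
Lymphovascular invasion: Present,47,56,49,71,0.839,0.690,-0.011,0.309,0.083
Stage: IB,1,56,58,71,0.018,0.817,-0.911,-0.687,<0.001
Stage: II,0,56,4,71,0.000,0.056,-0.126,0.013,0.196
Stage: III,40,56,0,71,0.714,0.000,0.580,0.849,<0.001
Stage: IV,4,56,0,71,0.071,0.000,-0.012,0.155,0.076
Stage: Relapse,7,56,5,71,0.125,0.070,-0.066,0.176,0.460
Stage: Post-RT/CT,4,56,4,71,0.071,0.056,-0.086,0.116,0.999
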