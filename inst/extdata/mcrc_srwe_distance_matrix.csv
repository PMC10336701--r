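treatment_study,Dong 2015,Matsumoto 2007,Catalano 2009,Fuse 2008,Suenaga 2008,Fuse 2007,Hochster 2003,Yoshino 2007
Bendell 2012 (1),0.029,0.273,0.048,0.134,0.077,0.126,0.043,0.057
Bendell 2012 (2),0.034,0.273,0.043,0.139,0.074,0.131,0.041,0.062
Hurwitz 2014,0.151,0.156,0.158,0.211,0.171,0.248,0.169,0.179
Van Cutsem 2009 (1),0.051,0.234,0.092,0.093,0.040,0.085,0.073,0.018
Van Cutsem 2009 (2),0.034,0.232,0.085,0.082,0.044,0.074,0.083,0.018
Van Cutsem 2009 (3),0.047,0.221,0.096,0.072,0.045,0.064,0.094,0.013
Van Cutsem 2009 (4),0.051,0.224,0.095,0.079,0.045,0.071,0.087,0.017
Bennouna 2017 (1),0.058,0.227,0.069,0.110,0.073,0.102,0.089,0.041
Bennouna 2017 (2),0.208,0.115,0.208,0.175,0.204,0.212,0.242,0.191
Buchler 2014 (1),0.045,0.233,0.079,0.094,0.070,0.086,0.080,0.025
Buchler 2014 (2),0.052,0.213,0.088,0.082,0.050,0.072,0.091,0.014
Ocvirk 2011 (1),0.043,0.260,0.072,0.100,0.066,0.094,0.066,0.065
Ocvirk 2011 (2),0.051,0.226,0.097,0.080,0.047,0.062,0.096,0.044
Moriwaki 2012 (1),0.204,0.062,0.233,0.121,0.160,0.148,0.243,0.165
Moriwaki 2012 (2),0.184,0.099,0.228,0.132,0.129,0.169,0.211,0.150
Kotaka 2016,0.068,0.200,0.095,0.072,0.033,0.064,0.104,0.034
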