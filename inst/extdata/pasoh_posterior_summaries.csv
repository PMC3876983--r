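season,parameter,q2.5,q25,q50,q75,q97.5
2002,a,0.0035,0.0045,0.0051,0.0059,0.0080
2002,b,0.7353,0.9209,1.0320,1.1548,1.4197
2002,delta,273.36,325.77,368.10,429.78,662.25
2002,sigma,1.5600,1.8484,2.0300,2.2064,2.6900
2002,d_ratio,11.40,30.46,61.61,130.09,1388.67
2002,N_ep,22.69,26.66,28.81,31.08,35.91
2005,a,0.0056,0.0075,0.0090,0.0109,0.0162
2005,b,0.5662,0.6923,0.7635,0.8464,1.0196
2005,delta,283.73,357.30,417.46,503.20,817.18
2005,sigma,0.9500,1.1230,1.2242,1.3356,1.5800
2005,d_ratio,2.47,3.53,4.48,5.95,12.14
2005,N_ep,33.97,40.40,44.15,48.16,56.49
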