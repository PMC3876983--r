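season,mother_id,A,m,s,allogamous,n_donors
2002,G482,48,0.596,0.021,0.383,18
2002,G549,20,0.125,0.100,0.775,12
2002,G822,48,0.500,0.000,0.500,22
2002,G973,45,0.263,0.029,0.708,24
2002,G1243,41,0.271,0.000,0.729,28
2002,G1783,48,0.419,0.023,0.558,24
2002,G1927,48,0.521,0.292,0.187,9
2002,G1928,34,0.333,0.053,0.614,7
2002,G2280,33,0.188,0.212,0.600,17
2005,G805,48,0.191,0.553,0.256,12
2005,G1025,48,0.521,0.042,0.437,21
2005,G1287,48,0.472,0.111,0.417,15
2005,G1535,48,0.422,0.022,0.556,25
2005,G1742,48,0.619,0.000,0.381,16
2005,G1783,48,0.575,0.050,0.375,15
2005,G1796,48,0.375,0.000,0.625,30
2005,G1860,48,0.684,0.000,0.316,12
2005,G1928,48,0.500,0.146,0.354,17
2005,G2517,48,0.271,0.458,0.271,13
2005,G2598,48,0.396,0.146,0.458,22
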