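"name","ex334","ex343","ex353","ex362","ex372","ex381","ex391","ex400","ex410","ex419","ex429","ex438","ex448","ex457","ex467","ex476","ex486","ex495"
"nadh_like",0.109181,0.150356,0.176444,0.176444,0.150356,0.109181,0.067559,0.035624,0.016007,0.006129,0.002,0.000556,0.000132,2.7e-05,5e-06,1e-06,0,0
"fad_like",0.000162,0.000522,0.001499,0.003856,0.008872,0.018268,0.033657,0.055492,0.081869,0.108083,0.127685,0.13498,0.127685,0.108083,0.081869,0.055492,0.033657,0.018268
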