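# serpentine capillary centerline, coordinates in micrometres
x,y,z
0,0,0
200,0,0
200,200,0
0,200,0
0,400,0
200,400,0
200,400,150
0,400,150
0,200,150
200,200,150
200,0,150
0,0,150
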