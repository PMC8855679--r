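run_index,point_type,absorbance,phenol_coded,acid_coded,water_coded
1,center,0.292,0,0,0
2,factorial,0.344,-1,-1,-1
3,factorial,0.256,1,-1,-1
4,factorial,0.044,1,-1,1
5,axial,0.043,0,-1.682,0
6,center,0.31,0,0,0
7,center,0.292,0,0,0
8,axial,0.221,0,1.682,0
9,axial,0.249,-1.682,0,0
10,axial,0.378,0,0,-1.682
11,center,0.29,0,0,0
12,factorial,0.232,1,1,1
13,axial,0.069,0,0,1.682
14,factorial,0.048,-1,-1,1
15,factorial,0.328,1,1,-1
16,factorial,0.26,-1,1,-1
17,center,0.269,0,0,0
18,factorial,0.224,-1,1,1
19,axial,0.287,1.682,0,0
20,center,0.298,0,0,0
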