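nos,scenario,case,weight,cost,n,mean,letters
1,3,2,1,9174,10,90.626,A
2,2,2,1,5940,10,89.913,AB
3,1,2,1,6864,10,89.898,AB
4,1,7,0.8,5940,10,88.192,ABC
5,1,5,0.5,5676,10,88.161,ABC
6,1,6,0.6,5742,10,88.144,ABC
7,2,7,0.8,5148,10,88.110,ABC
8,3,7,0.8,7029,10,86.089,ABCD
9,9,NA,NA,5296.5,100,85.810,ABCD
10,3,6,0.6,6748.5,10,84.832,BCDE
11,3,5,0.5,6451.5,10,83.584,CDE
12,3,4,0.4,5329.5,10,81.388,DE
13,2,6,0.6,4422,10,79.709,E
14,1,4,0.4,5280,10,70.144,F
15,1,3,0.2,4966.5,10,67.242,FG
16,2,5,0.5,3844.5,10,63.699,GH
17,2,4,0.4,3630,10,61.170,H
18,1,1,0,4521,10,45.982,I
19,3,3,0.2,4983,10,44.380,I
20,2,3,0.2,2755.5,10,40.379,I
21,2,1,0,2161.5,10,31.216,J
22,3,1,0,3943.5,10,14.969,K
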