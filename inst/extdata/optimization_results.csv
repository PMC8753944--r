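scenario,case,w_cost,w_sat,lambda,z_cost,z_sat
1,1,1,0,NA,4521,45.9
1,2,0,1,NA,6864,89.95
1,3,0.8,0.2,1,4966.5,67.2
1,4,0.6,0.4,1,5280,70.1
1,5,0.5,0.5,1,5676,88.1
1,6,0.4,0.6,1,5742,88.17
1,7,0.2,0.8,1,5940,88.2
2,1,1,0,NA,2161.5,31.2
2,2,0,1,NA,5940,89.9
2,3,0.8,0.2,1,2755.5,40.4
2,4,0.6,0.4,1,3630,61.2
2,5,0.5,0.5,1,3844.5,63.7
2,6,0.4,0.6,1,4422,79.7
2,7,0.2,0.8,1,5148,88.1
3,1,1,0,NA,3943.5,14.97
3,2,0,1,NA,9174,90.62
3,3,0.8,0.2,1,4983,44.4
3,4,0.6,0.4,1,5329.5,81.4
3,5,0.5,0.5,1,6451.5,83.6
3,6,0.4,0.6,1,6748.5,84.8
3,7,0.2,0.8,1,7029,86.1
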