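label,b601,a602,a603,a604,b606,b607,b608,b609,a610,a611,a612
b601,17037.9,35.6,-0.6,-0.8,-0.7,-0.8,1.9,1.8,-3.5,3.1,5.8
a602,35.6,16532.1,50.5,4.2,3.8,4.4,-5.6,-21.6,-5.7,-2.2,7.3
a603,-0.6,50.5,16553.1,-5.7,-8.2,-8.0,2.1,58.3,6.5,-0.4,-2.4
a604,-0.8,4.2,-5.7,16469.8,46.7,21.7,-2.3,0.5,-3.0,-2.0,1.6
b606,-0.7,3.8,-8.2,46.7,17088.1,22.8,-4.1,4.2,-2.1,-1.7,1.6
b607,-0.8,4.4,-8.0,21.7,22.8,17113.1,-2.3,0.2,-1.0,-1.7,1.7
b608,1.9,-5.6,2.1,-2.3,-4.1,-2.3,16888.0,25.1,51.4,3.9,-1.9
b609,1.8,-21.6,58.3,0.5,4.2,0.2,25.1,16676.3,-0.5,2.5,-0.4
a610,-3.5,-5.7,6.5,-3.0,-2.1,-1.0,51.4,-0.5,16397.1,-26.3,39.9
a611,3.1,-2.2,-0.4,-2.0,-1.7,-1.7,3.9,2.5,-26.3,16586.7,89.4
a612,5.8,7.3,-2.4,1.6,1.6,1.7,-1.9,-0.4,39.9,89.4,16636.4
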