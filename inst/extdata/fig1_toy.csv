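source,target,layer,weight
x1,x2,black,1
x1,x3,black,1
x1,x4,black,1
x1,y1,black,1
x1,y2,black,1
x2,x1,black,1
x2,x3,black,1
x2,x4,black,1
x2,y2,black,1
x2,y3,black,1
x3,x1,black,1
x3,x2,black,1
x3,x4,black,1
x3,y3,black,1
x4,x1,black,1
x4,x2,black,1
x4,x3,black,1
x4,y4,black,1
y1,x1,black,1
y1,y2,black,1
y1,y3,black,1
y1,y4,black,1
y2,x1,black,1
y2,x2,black,1
y2,y1,black,1
y2,y3,black,1
y2,y4,black,1
y3,x2,black,1
y3,x3,black,1
y3,y1,black,1
y3,y2,black,1
y3,y4,black,1
y4,x4,black,1
y4,y1,black,1
y4,y2,black,1
y4,y3,black,1
z1,z2,black,1
z1,z3,black,1
z1,z4,black,1
z2,z1,black,1
z2,z3,black,1
z2,z4,black,1
z3,z1,black,1
z3,z2,black,1
z3,z4,black,1
z4,z1,black,1
z4,z2,black,1
z4,z3,black,1
x1,x2,red,1
x1,x3,red,1
x1,x4,red,1
x1,y1,red,1
x1,y2,red,1
x2,x1,red,1
x2,x3,red,1
x2,x4,red,1
x2,y2,red,1
x2,y3,red,1
x3,x1,red,1
x3,x2,red,1
x3,x4,red,1
x3,y3,red,1
x4,x1,red,1
x4,x2,red,1
x4,x3,red,1
x4,y4,red,1
y1,x1,red,1
y1,y2,red,1
y1,y3,red,1
y1,y4,red,1
y2,x1,red,1
y2,x2,red,1
y2,y1,red,1
y2,y3,red,1
y2,y4,red,1
y3,x2,red,1
y3,x3,red,1
y3,y1,red,1
y3,y2,red,1
y3,y4,red,1
y4,x4,red,1
y4,y1,red,1
y4,y2,red,1
y4,y3,red,1
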