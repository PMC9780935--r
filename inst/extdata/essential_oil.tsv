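compound	alt_name	rt	relative_area
alpha-pinene	pin-2,3-ene	9.12	0.57
beta-phellandrene	p-menthane-2,7-diene	10.43	0.75
beta-pinene	pin-2,10-ene	11.07	1.52
octanal	octanal	11.42	0.23
delta-3-carene	car-3,4-ene	11.56	0.14
m-cymene	m-menthane-1,3,5-triene	12.03	0.01
limonene	p-mentha-1,8-diene	12.26	96.45
gamma-terpinene	p-menthane-1,4-diene	13.04	0.07
linalool	3,7-dimethylocta-1,6-dien-3-ol	14.21	0.27
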