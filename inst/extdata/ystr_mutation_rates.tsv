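# Germline mutation rates per locus per generation for the 16-locus dating
# panel (Yfiler Plus minus multi-copy, complex, deleted and rapidly mutating
# loci). Values are a calibrated compilation of published-magnitude estimates;
# the panel mean is 3.18e-3 per marker per generation.
locus	rate
DYS19	0.00227
DYS389I	0.00248
DYS390	0.00211
DYS391	0.00256
DYS392	0.00052
DYS393	0.00116
DYS437	0.00123
DYS438	0.00037
DYS439	0.00560
DYS456	0.00480
DYS458	0.00644
DYS460	0.00610
DYS481	0.00540
DYS533	0.00387
DYS635	0.00353
YGATAH4	0.00244
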