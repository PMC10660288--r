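term	tissue_category	system_category
hippocampus	brain	nervous
cortex	brain	nervous
cerebellum	brain	nervous
dorsolateral prefrontal cortex	brain	nervous
substantia nigra	brain	nervous
spinal cord	spinal cord	nervous
tibial nerve	peripheral nerve	nervous
heart	heart	cardiovascular
left ventricle	heart	cardiovascular
aorta	blood vessel	cardiovascular
coronary artery	blood vessel	cardiovascular
whole blood	blood	hematopoietic
monocyte	blood	hematopoietic
t cell	blood	hematopoietic
b cell	blood	hematopoietic
spleen	spleen	hematopoietic
liver	liver	digestive
pancreas	pancreas	digestive
stomach	stomach	digestive
colon	intestine	digestive
small intestine	intestine	digestive
esophagus	esophagus	digestive
lung	lung	respiratory
kidney	kidney	renal
skeletal muscle	muscle	musculoskeletal
adipose	adipose	adipose
subcutaneous adipose	adipose	adipose
skin	skin	integumentary
fibroblast	skin	integumentary
thyroid	thyroid	endocrine
adrenal gland	adrenal gland	endocrine
pituitary	pituitary	endocrine
testis	testis	reproductive
ovary	ovary	reproductive
lymphoblastoid cell line	cell line	cell line
ipsc	cell line	cell line
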