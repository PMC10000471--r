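c385	fusion_copies	fut2_genotype	secretor_phenotype	c59	c314	fut3_genotype	lewis_phenotype	count
A/A	0	Se/Se	Secretor	T/T	C/C	Le/Le	Le(a-b+)	11
A/A	0	Se/Se	Secretor	T/T	C/T	Le/le^202,314	Le(a-b+)	2
A/A	0	Se/Se	Secretor	T/G	C/C	Le/le^59	Le(a-b+)	7
A/A	0	Se/Se	Secretor	T/G	C/T	le^59/le^202,314	Le(a-b-)	1
A/A	0	Se/Se	Secretor	G/G	C/C	le^59/le^59	Le(a-b-)	3
A/T	0	Se/Se^w	Secretor	T/T	C/C	Le/Le	Le(a-b+)	13
A/T	0	Se/Se^w	Secretor	T/G	C/C	Le/le^59	Le(a-b+)	19
A/T	0	Se/Se^w	Secretor	G/G	C/C	le^59/le^59	Le(a-b-)	6
T/T	0	Se^w/Se^w	Weak secretor	T/T	C/C	Le/Le	Le(a+b+)	9
T/T	0	Se^w/Se^w	Weak secretor	T/G	C/C	Le/le^59	Le(a+b+)	5
T/T	0	Se^w/Se^w	Weak secretor	G/G	C/C	le^59/le^59	Le(a-b-)	8
A/A	1	Se/se^fus	Secretor	T/T	C/C	Le/Le	Le(a-b+)	2
A/A	1	Se/se^fus	Secretor	T/G	C/C	Le/le^59	Le(a-b+)	6
A/A	1	Se/se^fus	Secretor	G/G	C/C	le^59/le^59	Le(a-b-)	1
T/T	1	Se^w/se^fus	Weak secretor	T/G	C/C	Le/le^59	Le(a+b+)	2
A/A	2	se^fus/se^fus	Non-secretor	T/G	C/C	Le/le^59	Le(a+b-)	1
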