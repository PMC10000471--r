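# Shipped fixtures

`cohort_genotypes_japanese96.tsv` — genotype configuration table for a
96-subject Japanese reference cohort used as the package's validation
fixture: 16 genotype configurations with subject counts summing to 96.
Columns: observed c.385 base pair, fusion-allele copy number, FUT2 genotype
label, expected secretor phenotype, c.59T>G and c.314C>T genotypes, FUT3
genotype label, expected Lewis phenotype, subject count.

Genotype marginals implied by the table: FUT2 — 24 385A/A, 38 385A/T,
22 385T/T, 9 385A/fusion, 2 385T/fusion, 1 fusion/fusion; FUT3 —
37 59T/T, 41 59T/G, 18 59G/G and 93 314C/C, 3 314C/T.

The expected-phenotype columns are what the genotype-to-phenotype rules
should reproduce; they are used as reference output in the test suite, not
as input to the inference. One cohort subject recorded here as Se/Se^w is
known (by sequencing) to carry a rare null allele, se^628, outside the
probe window; the assay cannot distinguish it from Se, and the table
records the assay-level genotype.
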