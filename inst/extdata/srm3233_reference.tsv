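# Published reference values for NIST SRM 3233 (Fortified Breakfast
# Cereal), g per 100 g fresh weight: certificate-of-analysis (COA)
# carbohydrate attributes and the bottom-up LC-MS polysaccharide
# determinations, with their published totals.
source	attribute	value	uncertainty
COA	total_carbohydrates	79.23	1.04
COA	total_sugars	16.07	1.53
COA	lmw_sdf	3.07	0.62
COA	estimated_polysaccharide_printed	60.08	1.95
FITDOG	starch	55.92	2.54
FITDOG	cellulose	1.88	0.63
FITDOG	beta-glucan	1.48	0.29
FITDOG	xylan	0.59	0.07
FITDOG	arabinan	0.10	0.02
FITDOG	mannan	0.03	0.01
FITDOG	chitin	0.01	0.01
FITDOG	total_polysaccharide_printed	60.02	2.63
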