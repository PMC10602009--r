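subline	repetition	cross_id	generation	mother_class	father_class	phenotype	count
subA	1	F3	F4	ACOS(mCe-mVe)	FIRE(mC/Y)	-	16
subA	1	F3	F4	ACOS(mCe-mVe)	FIRE(mC/Y)	mC	15
subA	1	F3	F4	ACOS(mCe-mVe)	FIRE(mC/Y)	mC,mCe,mVe	11
subA	1	F3	F4	ACOS(mCe-mVe)	FIRE(mC/Y)	mCe,mVe	8
subA	1	F4	F5	ACOS(mCe-mVe); FIRE(mC)	wildtype	-	12
subA	1	F4	F5	ACOS(mCe-mVe); FIRE(mC)	wildtype	mC	10
subA	1	F4	F5	ACOS(mCe-mVe); FIRE(mC)	wildtype	mC,mCe	5
subA	1	F4	F5	ACOS(mCe-mVe); FIRE(mC)	wildtype	mC,mVe	11
subA	1	F4	F5	ACOS(mCe-mVe); FIRE(mC)	wildtype	mCe	6
subA	1	F4	F5	ACOS(mCe-mVe); FIRE(mC)	wildtype	mVe	6
subA	1	F5	F6	ACOS(mCe)	ACOS(mVe)	-	16
subA	1	F5	F6	ACOS(mCe)	ACOS(mVe)	mCe	11
subA	1	F5	F6	ACOS(mCe)	ACOS(mVe)	mCe,mVe	11
subA	1	F5	F6	ACOS(mCe)	ACOS(mVe)	mVe	12
subA	1	F6	F7	ACOS(mCe/mVe)	ACOS(mCe/mVe)	mCe	11
subA	1	F6	F7	ACOS(mCe/mVe)	ACOS(mCe/mVe)	mCe,mVe	19
subA	1	F6	F7	ACOS(mCe/mVe)	ACOS(mCe/mVe)	mVe	20
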