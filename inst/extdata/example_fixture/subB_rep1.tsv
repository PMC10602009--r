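subline	repetition	cross_id	generation	mother_class	father_class	phenotype	count
subB	1	F3	F4	ACOS(mCe-mVe)	FIRE(mC/Y)	-	12
subB	1	F3	F4	ACOS(mCe-mVe)	FIRE(mC/Y)	mC	17
subB	1	F3	F4	ACOS(mCe-mVe)	FIRE(mC/Y)	mC,mCe,mVe	12
subB	1	F3	F4	ACOS(mCe-mVe)	FIRE(mC/Y)	mCe,mVe	9
subB	1	F4	F5	ACOS(mCe-mVe); FIRE(mC)	wildtype	-	11
subB	1	F4	F5	ACOS(mCe-mVe); FIRE(mC)	wildtype	mC	13
subB	1	F4	F5	ACOS(mCe-mVe); FIRE(mC)	wildtype	mC,mCe	8
subB	1	F4	F5	ACOS(mCe-mVe); FIRE(mC)	wildtype	mC,mVe	8
subB	1	F4	F5	ACOS(mCe-mVe); FIRE(mC)	wildtype	mCe	4
subB	1	F4	F5	ACOS(mCe-mVe); FIRE(mC)	wildtype	mVe	6
subB	1	F5	F6	ACOS(mCe)	ACOS(mVe)	-	15
subB	1	F5	F6	ACOS(mCe)	ACOS(mVe)	mCe	8
subB	1	F5	F6	ACOS(mCe)	ACOS(mVe)	mCe,mVe	17
subB	1	F5	F6	ACOS(mCe)	ACOS(mVe)	mVe	10
subB	1	F6	F7	ACOS(mCe/mVe)	ACOS(mCe/mVe)	mCe,mVe	31
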