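subline	repetition	cross_id	generation	mother_class	father_class	phenotype	count
gruulA	1	F7a	F8	AGOC(mO/mO)	ACOS(mCe/mCe)	mCe,mO	50
gruulA	1	F7b	F8	AGOC(mC/mC)	ACOS(mVe/mVe)	mC,mVe	50
gruulA	1	F8	F9	AGOC(mO); ACOS(mCe)	AGOC(mC); ACOS(mVe)	-	4
gruulA	1	F8	F9	AGOC(mO); ACOS(mCe)	AGOC(mC); ACOS(mVe)	mC	2
gruulA	1	F8	F9	AGOC(mO); ACOS(mCe)	AGOC(mC); ACOS(mVe)	mC,mCe	3
gruulA	1	F8	F9	AGOC(mO); ACOS(mCe)	AGOC(mC); ACOS(mVe)	mC,mCe,mO	8
gruulA	1	F8	F9	AGOC(mO); ACOS(mCe)	AGOC(mC); ACOS(mVe)	mC,mCe,mO,mVe	1
gruulA	1	F8	F9	AGOC(mO); ACOS(mCe)	AGOC(mC); ACOS(mVe)	mC,mCe,mVe	2
gruulA	1	F8	F9	AGOC(mO); ACOS(mCe)	AGOC(mC); ACOS(mVe)	mC,mO	4
gruulA	1	F8	F9	AGOC(mO); ACOS(mCe)	AGOC(mC); ACOS(mVe)	mC,mO,mVe	3
gruulA	1	F8	F9	AGOC(mO); ACOS(mCe)	AGOC(mC); ACOS(mVe)	mC,mVe	4
gruulA	1	F8	F9	AGOC(mO); ACOS(mCe)	AGOC(mC); ACOS(mVe)	mCe	1
gruulA	1	F8	F9	AGOC(mO); ACOS(mCe)	AGOC(mC); ACOS(mVe)	mCe,mO	3
gruulA	1	F8	F9	AGOC(mO); ACOS(mCe)	AGOC(mC); ACOS(mVe)	mCe,mO,mVe	2
gruulA	1	F8	F9	AGOC(mO); ACOS(mCe)	AGOC(mC); ACOS(mVe)	mCe,mVe	2
gruulA	1	F8	F9	AGOC(mO); ACOS(mCe)	AGOC(mC); ACOS(mVe)	mO	2
gruulA	1	F8	F9	AGOC(mO); ACOS(mCe)	AGOC(mC); ACOS(mVe)	mO,mVe	3
gruulA	1	F8	F9	AGOC(mO); ACOS(mCe)	AGOC(mC); ACOS(mVe)	mVe	6
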