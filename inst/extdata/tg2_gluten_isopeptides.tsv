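id	grain	tg2_lysine	tg2_peptide	gluten_peptide	gpt	accession	uniprot_name	organism	mq_score	q_pos	q_ambiguous	deamidation	deamidation_ambiguous	prm_localized	unspecific_cterm	note
W1	wheat	K205	FLKNAGR	WQIPEQSR	alpha-gliadins	P04726	alpha/beta-gliadin clone PW1215	T. aestivum	49.37	2				FALSE	FALSE
W2	wheat	K205	FLKNAGR	AQIPQQL	gamma-gliadins	A0A290XYW2	gamma-gliadin	T. aestivum	66.99	2				FALSE	FALSE
W3	wheat	K205	FLKNAGR	VQGQGIIQPQQPAQL	gamma-gliadins	P08453	gamma-gliadin	T. aestivum	91.31	10		4		FALSE	FALSE	crosslink Q10 94.4%, deamidation Q4 99.9%
W4	wheat	K265	WKNHGCQR	PYSQPQPF	LMW-GS	X2KVH9	alpha-gliadin	T. aestivum	59.2	4				FALSE	FALSE
W5	wheat	K429	ISTKSVGR	PQQTFPQQPLF	omega1,2-gliadins	R9XUE1	LMW-GS	T. aestivum	84.57	8				FALSE	FALSE	typeset bold marks Q3; QP-motif grouping and site figure place the crosslink at Q8
W6	wheat	K468	LAEKEETGMAMR	PQPPQQPF	gamma-gliadins	A0A290XYS8	omega-gliadin	T. aestivum	75.31	2				FALSE	TRUE	unspecific cleavage at the C-terminal end
W7	wheat	K590	DLYLENPEIKIR	VQGQGIIQPQQPAQL	gamma-gliadins	P08453	gamma-gliadin	T. aestivum	61.21	10				FALSE	FALSE
W8	wheat	K590	DLYLENPEIKIR	QEQQIGQEQQPGQW	alpha-gliadins	B2LS24	HMW glutenin subunit type-2	T. timopheevii	55.26	9		1		TRUE	FALSE	deamidation site from figure; motif-neutral context
W9	wheat	K600	QKR	PQQSEQVIPQQPQQPF	gamma-gliadins	A0A3B6UD61	uncharacterized protein	T. aestivum	104.05	6		10		TRUE	FALSE	deamidation in preferred QXP context
W10	wheat	K600	QKR	QQQPPFWQQQPPF	LMW-GS	I3QPH0	low molecular weight glutenin subunit t128	T. aestivum	70.94	3		8		TRUE	FALSE	deamidation in poor QXXP context
W11	wheat	K677	AVKGFR	RPQQPYPQPQPQY	alpha-gliadins	A0A023WGB8	alpha-gliadin	T. aestivum	63.73	4				FALSE	FALSE	typeset bold marks Q3; QP-motif grouping places the crosslink at Q4
W12	wheat	K677	AVKGFR	WQTPEQSR	alpha-gliadins	I0IT59	alpha/beta-gliadin	T. aestivum	64.42	2				FALSE	FALSE
W13	wheat	K677	AVKGFR	VYYPTSPQQPGQL	HMW-GS	A0A1G4P1W4	HMW glutenin x-type subunit 1Bx6	T. aestivum	69.45	8				FALSE	FALSE
R1	rye	K205	FLKNAGR	IVQGQSIIQQQPAQL	gamma-40k-secalins	H8Y0N7	gamma prolamin	S. cereale ssp. afghanicum	68.97	5		10		TRUE	FALSE	deamidation in preferred QXP context
R2	rye	K429	ISTKSVGR	AQVQGIIQPQQL	gamma-75k-secalins	A4GU91	75k gamma secalin	S. sylvestre	59.25	2				TRUE	FALSE
R3	rye	K600	QKR	QPQQPFPQQPQQSF	gamma-75k-secalins	H8Y0K1	gamma prolamin	P. juncea	80.75	12		4,11		TRUE	FALSE	deamidations in QP and QXXF contexts
R4	rye	K677	AVKGFR	AQVQGIIQPQQL	gamma-75k-secalins	A4GU91	75k gamma secalin	S. sylvestre	90.05	2				TRUE	FALSE
R5	rye	K677	AVKGFR	QIPTPLQPQQPF	omega-secalins	Q41210	C-hordein	H. vulgare	57.18	1				FALSE	FALSE	crosslink localized at 99.3%
R6	rye	K677	AVKGFR	AQIPQHL	gamma-40k-secalins	H8Y0N7	gamma prolamin	S. cereale ssp. afghanicum	62.98	2				FALSE	FALSE	crosslink localized at 100%
B1	barley	K205	FLKNAGR	QGQQGQQLGQGQQGYY	D-hordeins	A0A2C9PIB7	high-molecular-weight glutenin subunit protein	Ae. umbellulata	59.9	7		12		TRUE	FALSE	deamidation in QXXF(Y) context
B2	barley	K265	WKNHGCQR	VQQQQPPF	B-hordeins	V9P6N2	LMW-i glutenin subunit 1	T. aestivum	85.85	2		4		FALSE	FALSE	deamidation in preferred QXP context
B3	barley	K590	DLYLENPEIKIR	PQQPGQW	D-hordeins	I6TRS8	D-hordein	H. vulgare	44.97	2				FALSE	FALSE
B4	barley	K590	DLYLENPEIKIR	IIPQQPQQPFPLQPHQPY	gamma-hordeins	P17991	C-hordein	H. vulgare	44.2		4,5			FALSE	FALSE	both crosslinking sites possible (49.3% each); PRM transitions not detectable
B5	barley	K600	QKR	PQQPGQGQQPGQR	D-hordeins	I6TRS8	D-hordein	H. vulgare	121.2	2		8		FALSE	FALSE	typeset bold marks Q3; QXP-motif grouping places the crosslink at Q2; deamidation in QXP context
B6	barley	K600	QKR	PQQPGQGQGQQGYYPGATSL	D-hordeins	I6TRS8	D-hordein	H. vulgare	82.36		10,11	8	10,11	FALSE	FALSE	deamidation Q8 at 77.4%; second deamidation and crosslink ambiguous between Q10/Q11
B7	barley	K677	AVKGFR	PLQPQQPFPW	gamma-hordeins	Q41210	C-hordein	H. vulgare	72.55	5				TRUE	FALSE
B8	barley	K677	AVKGFR	PQQQFPQQQFHQQQL	gamma-hordeins	A0A0B5JD29	omega-gliadin	T. aestivum	52.73	9		2,3,12	13,14	TRUE	FALSE	crosslink at Q9 by PRM b6-b9; deamidations Q2/Q3 by b2-b4; fourth deamidation ambiguous Q13/Q14
B9	barley	K677	AVKGFR	FPQYQIPTPL	gamma-hordeins	Q40053	Hor1-17 C-hordein	H. vulgare	47.94	3		5		TRUE	FALSE	deamidation in preferred QXP context
B10	barley	K677	AVKGFR	PQQPGQGQGQQGYYPGATSL	D-hordeins	I6TRS8	D-hordein	H. vulgare	106.36	10		6		TRUE	FALSE	deamidation site from figure; motif-neutral context
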