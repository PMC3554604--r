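surface	vocabulary	identifier	preferred_label
influenza like illness	MedDRA	10022004	influenza like illness
influenza-like illness	MedDRA	10022004	influenza like illness
flu-like illness	MedDRA	10022004	influenza like illness
flu-like symptoms	MedDRA	10022004	influenza like illness
influenza like symptoms	MedDRA	10022004	influenza like illness
influenza like illness	OAE	OAE_0000100	influenza like illness AE
influenza like illness AE	OAE	OAE_0000100	influenza like illness AE
flu-like illness	OAE	OAE_0000100	influenza like illness AE
flu-like symptoms	OAE	OAE_0000100	influenza like illness AE
influenza like symptoms	OAE	OAE_0000100	influenza like illness AE
influenza	MedDRA	10022000	influenza
nausea	MedDRA	10028813	nausea
nauseous	MedDRA	10028813	nausea
nausea	OAE	OAE_0009001	nausea AE
nausea AE	OAE	OAE_0009001	nausea AE
nauseous	OAE	OAE_0009001	nausea AE
rash	MedDRA	10037844	rash
macular rash	MedDRA	10037844	rash
skin rash	MedDRA	10037844	rash
rash	OAE	OAE_0009002	rash AE
rash AE	OAE	OAE_0009002	rash AE
macular rash	OAE	OAE_0009002	rash AE
skin rash	OAE	OAE_0009002	rash AE
pyrexia	MedDRA	10037660	pyrexia
fever	MedDRA	10037660	pyrexia
febrile	MedDRA	10037660	pyrexia
fever	OAE	OAE_0009003	fever AE
fever AE	OAE	OAE_0009003	fever AE
pyrexia	OAE	OAE_0009003	fever AE
vasculitis	MedDRA	10047115	vasculitis
vasculitis	OAE	OAE_0009004	vasculitis AE
vasculitis AE	OAE	OAE_0009004	vasculitis AE
hospitalization	OAE	OAE_0009005	hospitalization
patient hospitalization	OAE	OAE_0009005	hospitalization
patient hospitalized	OAE	OAE_0009005	hospitalization
hospitalized	OAE	OAE_0009005	hospitalization
arthralgia	MedDRA	10003239	arthralgia
joint pain	MedDRA	10003239	arthralgia
arthralgia	OAE	OAE_0009006	arthralgia AE
arthralgia AE	OAE	OAE_0009006	arthralgia AE
joint pain	OAE	OAE_0009006	arthralgia AE
injection site reaction	MedDRA	10022095	injection site reaction
injection site rxn	MedDRA	10022095	injection site reaction
injection site reaction	OAE	OAE_0009007	injection site reaction AE
injection site reaction AE	OAE	OAE_0009007	injection site reaction AE
injection site rxn	OAE	OAE_0009007	injection site reaction AE
headache	MedDRA	10019211	headache
head ache	MedDRA	10019211	headache
headache	OAE	OAE_0009008	headache AE
headache AE	OAE	OAE_0009008	headache AE
vomiting	MedDRA	10047700	vomiting
emesis	MedDRA	10047700	vomiting
vomiting	OAE	OAE_0009009	vomiting AE
vomiting AE	OAE	OAE_0009009	vomiting AE
emesis	OAE	OAE_0009009	vomiting AE
dizziness	MedDRA	10013573	dizziness
dizzy	MedDRA	10013573	dizziness
dizziness	OAE	OAE_0009010	dizziness AE
dizziness AE	OAE	OAE_0009010	dizziness AE
urticaria	MedDRA	10046735	urticaria
hives	MedDRA	10046735	urticaria
urticaria	OAE	OAE_0009011	urticaria AE
urticaria AE	OAE	OAE_0009011	urticaria AE
seizure	MedDRA	10039906	seizure
brief generalized seizure	MedDRA	10039906	seizure
convulsion	MedDRA	10039906	seizure
seizure	OAE	OAE_0009012	seizure AE
seizure AE	OAE	OAE_0009012	seizure AE
brief generalized seizure	OAE	OAE_0009012	seizure AE
Engerix-B	VO	VO_0010711	Engerix-B
engerix	VO	VO_0010711	Engerix-B
1st Engerix-B dose	VO	VO_0010711	Engerix-B
vaccinated w/Engerix-B	VO	VO_0010711	Engerix-B
MMR vaccine	VO	VO_0009101	MMR vaccine
MMR	VO	VO_0009101	MMR vaccine
measles mumps rubella vaccine	VO	VO_0009101	MMR vaccine
vaccinated w/MMR	VO	VO_0009101	MMR vaccine
DTP vaccine	VO	VO_0009102	DTP vaccine
DTP	VO	VO_0009102	DTP vaccine
vaccinated w/DTP	VO	VO_0009102	DTP vaccine
HEP B vaccine	VO	VO_0009103	HEP B vaccine
HEP B	VO	VO_0009103	HEP B vaccine
hepatitis B vaccine	VO	VO_0009103	HEP B vaccine
vaccinated w/HEP B	VO	VO_0009103	HEP B vaccine
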