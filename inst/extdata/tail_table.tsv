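taxon	group	NC	TP	E	PZ	C	twofold	trpt
Gorgosaurus_libratus	Tyrannosauridae	31 (+4)	13	-	-	-	No	No
Tyrannosaurus_rex	Tyrannosauridae	>34	16	-	-	-	No	No
Huaxiagnathus_orientalis	Compsognathidae	>25	17	-	-	-	No	No
Sinocalliopteryx_gigas	Compsognathidae	49	16	-	-	-	No	No
Sinosauropteryx_prima	Compsognathidae	>64	17	-	-	-	No	No
Gallimimus_bullatus	Ornithomimosauria	36-39	14	-	-	-	No	Yes
Harpymimus_okladnikovi	Ornithomimosauria	>34	12	-	-	-	No	Yes
Shenzhousaurus_orientalis	Ornithomimosauria	>16	11	-	-	-	No	Yes
Alxasaurus_elesitaiensis	Therizinosauroidea	>19	13	-	-	-	No	No
Beipiaosaurus_inexpectus	Therizinosauroidea	30	?	-	-	-	No	No
Neimongosaurus_yangi	Therizinosauroidea	22 (+3 to 8)	>12	-	-	-	No	No
Nothronychus_graffami	Therizinosauroidea	23 (+3)	12	-	-	-	No	No
Caudipteryx_sp	Oviraptorosauria	9	-	-	-	-	No	No
Khaan_mckennai	Oviraptorosauria	26 (+2)	21	-	-	-	No	No
Nomingia_gobiensis	Oviraptorosauria	24	18	-	-	-	No	No
Archaeopteryx_sp	Avialae	22	5	6	-	-	Yes	Yes
Epidendrosaurus_ningchengensis	Avialae	22 (+5?)	2	?	-	-	Yes	Yes
Jeholornis_prima	Avialae	24-27	2	3	-	-	Yes	Yes
Anchiornis_huxleyi	Troodontidae	20 (+6?)	3	5	-	-	Yes	Yes
Sinornithoides_dongi	Troodontidae	27	9	9	-	-	Yes	Yes
Buitreraptor_gonzalezorum	Unenlagiinae	>14	5	8	-	-	Yes	Yes
Rahonavis_ostromi	Unenlagiinae	>13	6	6	-	-	Yes	Yes
Cryptovolans_pauli	Microraptoria	28-20	?	5	?	4	Yes	Yes
Microraptor_gui	Microraptoria	approx. 26	?	4-6	?	?	Yes	Yes
Microraptor_zhaoianus	Microraptoria	24-26	6	6	6	3	Yes	Yes
Tianyuraptor_ostromi	Microraptoria	>25	?	7	?	3	Yes	Yes
Bambiraptor_feinbergorum	Eudromaeosauria	>23	6	10	9	6	Yes	Yes
Deinonychus_antirrhopus	Eudromaeosauria	36 (+4)	10	9	>10	8	No	Yes
Tsaagan_sp	Eudromaeosauria	>20	>12	>8	>10	6	No	Yes
Velociraptor_mongoliensis	Eudromaeosauria	approx. 30	11	6	10	6	No	Yes
UMNH_VP_20209	Eudromaeosauria	?	?	?	>8	>7	?	?
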