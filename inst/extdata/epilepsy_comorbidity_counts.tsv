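# Published literature co-occurrence counts for epilepsy and its comorbidities.
# One row per disease query; the epilepsy row is the index disease and carries
# the 2901-gene denominator (no comorbidity columns). Reported rates are
# percentages truncated at two decimals. The stroke row's reported rate is
# inconsistent with the column-4 count and the stated formula; it is kept
# verbatim and flagged downstream.
disease	mesh_id	n_documents	n_disease_genes	n_comorbidity_genes	reported_rate_percent
Epilepsy	D004827	192245	2901	NA	NA
Stroke	D020521	210846	4533	633	17.78
Alzheimer disease	D000544	109495	4968	396	13.65
Migraine	D008881	30928	1230	306	10.54
Parkinson disease	D010300	79103	3646	258	8.89
Hypertension	D006973	391190	5574	252	8.68
Dementia	D003704	183802	5833	220	7.58
Diabetes mellitus	D003920	394411	6661	184	6.34
Intestinal diseases	D007410	629691	9093	166	5.72
Thyroid diseases	D013959	153025	4366	133	4.58
Anxiety	D001007	84138	1782	124	4.27
Arthritis	D001168	259327	5367	122	4.2
Cataract	D002386	52150	2238	119	4.1
Asthma	D001249	147697	3761	86	2.96
Glaucoma	D005901	56679	2303	48	1.65
Depressive disorder, major	D003865	15706	1249	46	1.58
Urinary incontinence	D014549	34170	720	24	0.82
Peptic ulcer	D010437	68234	1445	21	0.72
Back pain	D001416	48516	1191	17	0.58
Pulmonary disease, chronic obstructive	D029424	35627	2244	15	0.51
Fibromyalgia	D005356	9021	468	10	0.34
Emphysema	D004646	25511	1261	9	0.31
Bronchitis, chronic	D029481	9085	580	2	0.06
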