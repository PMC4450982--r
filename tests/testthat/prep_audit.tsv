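molecule_id	valid	nha	n_rot_first	n_rot_second	differs_protonation	differs_tautomer	differs_ring_conformation	pairwise_rmsd
bio001	TRUE	38	17	17	FALSE	FALSE	FALSE	2.8792513144801863e-7
bio002	TRUE	22	9	9	FALSE	FALSE	FALSE	2.808832024838022e-7
bio003	TRUE	24	11	11	TRUE	FALSE	FALSE	2.5813747640247867e-7
bio004	TRUE	26	11	11	FALSE	FALSE	FALSE	2.776863572730247e-7
dec0001	TRUE	23	10	10	FALSE	FALSE	FALSE	2.6955895279189904e-7
dec0002	TRUE	23	10	10	TRUE	FALSE	FALSE	2.605339562549303e-7
dec0003	TRUE	31	14	14	FALSE	FALSE	FALSE	2.9634582596951166e-7
dec0004	TRUE	27	12	12	FALSE	FALSE	FALSE	2.8355915499901547e-7
dec0005	TRUE	28	11	11	FALSE	TRUE	FALSE	3.075009113294253e-8
dec0006	TRUE	37	17	17	FALSE	FALSE	FALSE	2.9114846322149646e-7
dec0007	TRUE	29	13	13	TRUE	FALSE	FALSE	2.5399514586007285e-7
dec0008	TRUE	40	18	18	FALSE	FALSE	FALSE	2.814064593896304e-7
dec0009	TRUE	38	17	17	FALSE	FALSE	TRUE	0.12396525683112888
dec0010	TRUE	29	13	13	TRUE	FALSE	FALSE	2.5438251805829e-7
dec0011	TRUE	36	16	16	FALSE	FALSE	FALSE	2.9479065995907377e-7
dec0012	TRUE	30	13	13	FALSE	FALSE	FALSE	2.930919862489495e-7
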