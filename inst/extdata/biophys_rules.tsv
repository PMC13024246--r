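# Rule table mapping headgroup class and acyl steric bins to qualitative biophysical labels.
# version: 1  (lookup: first row matching lipid_class with c_min<=total_c<=c_max and
# db_min<=total_db<=db_max).  Labels are ordinal {very low,low,average,high,very high},
# curvature {negative,neutral,positive}, fn {membrane component,lipid-mediated signaling},
# cellular_component {plasma membrane,ER,mitochondrion,other}.
# Bins encode standard headgroup/chain heuristics: bilayer thickness scales with total
# carbon; lateral diffusion scales inversely; >=4 double bonds thins/mobilizes one level;
# sn-1 ether linkage adds one level of rigidity; lyso and carnitine species are
# non-bilayer with positive intrinsic curvature.  Bin boundaries are approximate
# package defaults, editable by supplying a custom rules file.
lipid_class	c_min	c_max	db_min	db_max	bilayer_thickness	lateral_diffusion	intrinsic_curvature	fn	cellular_component	note
CAR	0	999	0	999	very low	very high	positive	lipid-mediated signaling	mitochondrion	acyl esters of carnitine; beta-oxidation shuttle, not a bilayer lipid
LPC	0	17	0	999	very low	very high	positive	lipid-mediated signaling	other	single short chain; inverted-cone lyso headgroup gives positive curvature
LPC	18	999	0	999	low	very high	positive	lipid-mediated signaling	other	single chain >= 18 C; lyso headgroup gives positive curvature
PC	0	30	0	3	very low	very high	neutral	membrane component	ER	diacyl PC, total C 0-30, <4 DB; length-scaled
PC	0	30	4	999	very low	very high	neutral	membrane component	ER	diacyl PC, total C 0-30, polyunsaturated; one level thinner/faster
PC O-	0	30	0	3	low	high	neutral	membrane component	other	alkyl-ether PC, total C 0-30, <4 DB; ether bond adds rigidity
PC O-	0	30	4	999	very low	very high	neutral	membrane component	other	alkyl-ether PC, total C 0-30, polyunsaturated
PC	31	34	0	3	low	high	neutral	membrane component	ER	diacyl PC, total C 31-34, <4 DB; length-scaled
PC	31	34	4	999	very low	very high	neutral	membrane component	ER	diacyl PC, total C 31-34, polyunsaturated; one level thinner/faster
PC O-	31	34	0	3	average	average	neutral	membrane component	other	alkyl-ether PC, total C 31-34, <4 DB; ether bond adds rigidity
PC O-	31	34	4	999	low	high	neutral	membrane component	other	alkyl-ether PC, total C 31-34, polyunsaturated
PC	35	38	0	3	average	average	neutral	membrane component	ER	diacyl PC, total C 35-38, <4 DB; length-scaled
PC	35	38	4	999	low	high	neutral	membrane component	ER	diacyl PC, total C 35-38, polyunsaturated; one level thinner/faster
PC O-	35	38	0	3	high	low	neutral	membrane component	other	alkyl-ether PC, total C 35-38, <4 DB; ether bond adds rigidity
PC O-	35	38	4	999	average	average	neutral	membrane component	other	alkyl-ether PC, total C 35-38, polyunsaturated
PC	39	42	0	3	high	low	neutral	membrane component	ER	diacyl PC, total C 39-42, <4 DB; length-scaled
PC	39	42	4	999	average	average	neutral	membrane component	ER	diacyl PC, total C 39-42, polyunsaturated; one level thinner/faster
PC O-	39	42	0	3	very high	very low	neutral	membrane component	other	alkyl-ether PC, total C 39-42, <4 DB; ether bond adds rigidity
PC O-	39	42	4	999	high	low	neutral	membrane component	other	alkyl-ether PC, total C 39-42, polyunsaturated
PC	43	999	0	3	very high	very low	neutral	membrane component	ER	diacyl PC, total C 43-999, <4 DB; length-scaled
PC	43	999	4	999	high	low	neutral	membrane component	ER	diacyl PC, total C 43-999, polyunsaturated; one level thinner/faster
PC O-	43	999	0	3	very high	very low	neutral	membrane component	other	alkyl-ether PC, total C 43-999, <4 DB; ether bond adds rigidity
PC O-	43	999	4	999	very high	very low	neutral	membrane component	other	alkyl-ether PC, total C 43-999, polyunsaturated
SM	0	34	0	999	average	low	neutral	membrane component	plasma membrane	sphingomyelin, total C <= 34; ordered-domain former, slow diffusion
SM	35	40	0	999	high	low	neutral	membrane component	plasma membrane	sphingomyelin, total C 35-40
SM	41	999	0	999	very high	very low	neutral	membrane component	plasma membrane	very-long-chain sphingomyelin, total C >= 41
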