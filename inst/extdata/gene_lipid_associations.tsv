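# Curated gene-lipid association table (synthetic stand-in for a metabolic
# reaction-path mapping; pairings follow standard enzyme-substrate class
# annotations, one provenance note per row).
# selector_type: species = exact canonical species name; class = all panel
# species of that headgroup class; subclass = all species with that LIPID MAPS
# subclass code.
gene	selector_type	selector_value	provenance
CPT2	class	CAR	carnitine palmitoyltransferase 2; regenerates acyl-CoA from acylcarnitines at the inner mitochondrial membrane
ABHD3	class	PC	alpha/beta hydrolase domain 3; phospholipase selective for medium-chain phosphatidylcholines
LPCAT1	class	LPC	lysophosphatidylcholine acyltransferase 1; reacylates LPC to PC (Lands cycle)
LPCAT2	class	LPC	lysophosphatidylcholine acyltransferase 2; LPC reacylation and PAF synthesis
LPCAT3	class	LPC	lysophosphatidylcholine acyltransferase 3; polyunsaturated LPC reacylation
LPCAT4	class	LPC	lysophosphatidylcholine acyltransferase 4; LPC reacylation
PNPLA6	class	LPC	patatin-like phospholipase 6 (neuropathy target esterase); lysophospholipase acting on LPC
ENPP6	class	LPC	ectonucleotide pyrophosphatase/phosphodiesterase 6; choline-specific glycerophosphodiesterase acting on lyso cholines
ENPP6	subclass	GP0102	ENPP6 also hydrolyzes choline ether lipids (alkyl glycerophosphocholines)
PLA2G4F	class	PC	cytosolic phospholipase A2 group IVF; releases sn-2 acyl chain from PC
PLA2G15	class	PC	lysosomal phospholipase A2; transacylase acting on glycerophosphocholines
LYPLA2	class	LPC	lysophospholipase A2; hydrolyzes LPC to glycerophosphocholine
PLAAT3	class	PC	phospholipase A/acyltransferase 3; PC hydrolysis and N-acylation
PNPLA8	class	PC	patatin-like phospholipase 8 (iPLA2-gamma); membrane PC remodeling
ABHD16A	class	PC	alpha/beta hydrolase domain 16A; glycerophospholipid lipase
SMPD3	class	SM	sphingomyelin phosphodiesterase 3 (neutral sphingomyelinase 2); hydrolyzes SM to ceramide
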