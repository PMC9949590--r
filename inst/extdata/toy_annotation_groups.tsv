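protein_id	group
Hxt1	transport
Gap1	transport
Pfk1	glycolysis
Pyk1	glycolysis
Pdc1	fermentation
Adh1	fermentation
Ald6	acetate metabolism
Acs1	acetate metabolism
Adk1	nucleotide metabolism
Pyc1	anaplerosis
Mdh2	redox shuttling
Mdh1	redox shuttling
Dic1	redox shuttling
Oac1	redox shuttling
Adh3	redox shuttling
Gut2	redox shuttling
Gpd1	glycerol metabolism
Gpd2	glycerol metabolism
Gpp1	glycerol metabolism
Mpc1	transport
Aac2	transport
Cat2	carnitine shuttle
Ach1	TCA cycle
Lsc1	TCA cycle
Cit1	TCA cycle
Idp1	TCA cycle
Pda1	TCA cycle
Cox1	oxidative phosphorylation
Sdh1	oxidative phosphorylation
Atp1	oxidative phosphorylation
Mae1	amino acid biosynthesis
Pos5	amino acid biosynthesis
Aro1	amino acid biosynthesis
Psa1	carbohydrate biosynthesis
Fas1	lipid biosynthesis
Are1	lipid biosynthesis
RIBOSOME	ribosome
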