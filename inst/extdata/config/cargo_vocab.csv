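label,synonyms
FITC,fitc;fluorescein isothiocyanate
fluorescein,
carboxyfluorescein,FAM;5-FAM
TAMRA,tamra;TMR
rhodamine,Rho;rhodamine B
DiI,Dil;dii
DiD,
Cy3,
Cy5,
Cy5.5,
Cy7,
Alexa488,
Alexa555,
Alexa594,
Alexa647,
NBD,
dansyl,
BODIPY,
coumarin,
dabcyl,
EGFP,
mCherry,
luciferase,
biotin,
quantum-dot,
gold-nanoparticle,
silver-nanoparticle,
iron-oxide-nanoparticle,
silica-nanoparticle,
polymeric-nanoparticle,
liposome,
micelle,
dendrimer,
exosome,
siRNA,si-RNA;small interfering RNA
miRNA,
mRNA,
plasmid-DNA,pDNA;plasmid
oligonucleotide,
antisense-oligo,
PNA,
PMO,
aptamer,
doxorubicin,
paclitaxel,
methotrexate,
cisplatin,
gemcitabine,
camptothecin,
curcumin,
insulin,
BSA,
ovalbumin,
streptavidin,
beta-galactosidase,
Cre-recombinase,
antibody-Fab,
cyclosporine,
vancomycin,
heparin,
TAM,
magnetic-bead,
peptide-nucleic-acid-clamp,
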