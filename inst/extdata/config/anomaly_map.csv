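token,replacement,type,observed
a,A,d-ala,TRUE
r,R,d-arg,TRUE
n,N,d-asn,TRUE
d,D,d-asp,TRUE
c,C,d-cys,TRUE
q,Q,d-gln,TRUE
e,E,d-glu,TRUE
g,G,d-gly,TRUE
h,H,d-his,TRUE
i,I,d-ile,TRUE
l,L,d-leu,TRUE
k,K,d-lys,TRUE
m,M,d-met,TRUE
f,F,d-phe,TRUE
p,P,d-pro,TRUE
s,S,d-ser,TRUE
t,T,d-thr,TRUE
w,W,d-trp,TRUE
y,Y,d-tyr,TRUE
v,V,d-val,TRUE
B,N,ambig-asx,TRUE
Z,Q,ambig-glx,TRUE
J,L,ambig-xle,TRUE
X,A,unknown-residue,TRUE
U,C,selenocysteine,TRUE
O,K,pyrrolysine,TRUE
[Orn],K,ornithine,TRUE
[Dab],K,diaminobutyrate,TRUE
[Dap],K,diaminopropionate,TRUE
[Cit],R,citrulline,TRUE
[hArg],R,homoarginine,TRUE
[Hyp],P,hydroxyproline,TRUE
[Nle],L,norleucine,TRUE
[Nva],V,norvaline,TRUE
[Aib],A,aminoisobutyrate,TRUE
[Sar],G,sarcosine,TRUE
[pSer],S,phosphoserine,TRUE
[pThr],T,phosphothreonine,TRUE
[pTyr],Y,phosphotyrosine,TRUE
[Hse],S,homoserine,TRUE
[Pen],C,penicillamine,TRUE
[Abu],A,aminobutyrate,TRUE
[Mpa],C,mercaptopropionate,TRUE
[MeLys],K,methyllysine,TRUE
[MeArg],R,methylarginine,TRUE
[AcLys],K,acetyllysine,TRUE
[Hle],L,homoleucine,FALSE
[Hph],F,homophenylalanine,FALSE
[Tha],A,thienylalanine,FALSE
[Nal],F,naphthylalanine,FALSE
[Bpa],F,benzoylphenylalanine,FALSE
[Cha],A,cyclohexylalanine,FALSE
[Dha],A,dehydroalanine,FALSE
[Pip],P,pipecolate,FALSE
[Tic],F,tetrahydroisoquinoline,FALSE
[Aad],E,aminoadipate,FALSE
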