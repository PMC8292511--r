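# nomtrans IUPAC token lexicon
# version: 1.0
# token<TAB>class
# classes: stem, suffix, prefix, multiplier, stereo, locant, punct, symbol
#
# parent-hydride stems, C1..C20, three surface forms each:
# full hydride (..ane), elided (..an, before vowel-initial suffixes),
# bare root (.., before -ene/-en locant groups)
meth	stem
methan	stem
methane	stem
eth	stem
ethan	stem
ethane	stem
prop	stem
propan	stem
propane	stem
but	stem
butan	stem
butane	stem
pent	stem
pentan	stem
pentane	stem
hex	stem
hexan	stem
hexane	stem
hept	stem
heptan	stem
heptane	stem
oct	stem
octan	stem
octane	stem
non	stem
nonan	stem
nonane	stem
dec	stem
decan	stem
decane	stem
undec	stem
undecan	stem
undecane	stem
dodec	stem
dodecan	stem
dodecane	stem
tridec	stem
tridecan	stem
tridecane	stem
tetradec	stem
tetradecan	stem
tetradecane	stem
pentadec	stem
pentadecan	stem
pentadecane	stem
hexadec	stem
hexadecan	stem
hexadecane	stem
heptadec	stem
heptadecan	stem
heptadecane	stem
octadec	stem
octadecan	stem
octadecane	stem
nonadec	stem
nonadecan	stem
nonadecane	stem
icos	stem
icosan	stem
icosane	stem
# ring and trivial parent stems
benzamide	stem
benzene	stem
purin	stem
purine	stem
pyrimidin	stem
pyrimidine	stem
Pyrimidine	stem
naphthalene	stem
pyrazole	stem
pyran	stem
adamantane	stem
# suffixes (written without the joining hyphen)
ol	suffix
one	suffix
al	suffix
ene	suffix
en	suffix
yl	suffix
# substituent / modifier prefixes
oxy	prefix
hydroxy	prefix
Hydroxy	prefix
oxo	prefix
amino	prefix
Amino	prefix
imino	prefix
Imino	prefix
anilino	prefix
acetyl	prefix
carbamoyl	prefix
chloro	prefix
Chloro	prefix
bromo	prefix
Bromo	prefix
fluoro	prefix
iodo	prefix
methyl	prefix
ethyl	prefix
propyl	prefix
butyl	prefix
pentyl	prefix
hexyl	prefix
methoxy	prefix
ethoxy	prefix
tert	prefix
hydro	prefix
phenyl	prefix
selena	prefix
# multiplying prefixes
di	multiplier
tri	multiplier
tetra	multiplier
# stereo descriptors
R	stereo
S	stereo
E	stereo
Z	stereo
# element-style / indicated-hydrogen symbols
N	symbol
H	symbol
O	symbol
λ	symbol
# locant digits
0	locant
1	locant
2	locant
3	locant
4	locant
5	locant
6	locant
7	locant
8	locant
9	locant
# punctuation
-	punct
,	punct
(	punct
)	punct
[	punct
]	punct
.	punct
'	punct
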