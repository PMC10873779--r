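# Common clinical UCUM unit codes (advisory membership list)
1
%
[pH]
kg
g
mg
ug
ng
pg
cm
mm
m
L
dL
mL
uL
mmol/L
umol/L
nmol/L
pmol/L
mol/L
mg/dL
g/dL
g/L
mg/L
ug/L
ng/mL
pg/mL
U/L
k[IU]/L
[IU]/L
mEq/L
meq/L
mm[Hg]
kPa
Cel
[degF]
/min
{beats}/min
{breaths}/min
10*3/uL
10*6/uL
10*9/L
10*12/L
s
min
h
d
wk
mo
a
mL/min
mL/min/{1.73_m2}
mmol/mol
%{Hb}
fL
pg/cell
kg/m2
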