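tf	synonym	cluster	evidence	flag
AraC		C1	strong
CsgD		C1	strong
FeaR		C1	strong
GadX		C1	strong
GalS		C1	strong
LsrR		C1	strong
MelR		C1	strong
Mlc		C1	strong
RclR	YkgD	C1	strong
AbgR		C1	weak
CdaR		C1	weak
FucR		C1	weak
MhpR		C1	weak
SrlR	GutR	C1	weak
HcaR		C1	weak
MtlR		C1	weak
PrpR		C1	weak
RhaR		C1	weak
TdcA		C1	weak
YiaJ		C1	weak
YeiL		C1	weak
YahB		C1	hypothetical
YbiI		C1	hypothetical
YneJ		C1	hypothetical
YgeV		C1	hypothetical
YgfI		C1	hypothetical
YihL		C1	hypothetical
ChpS		C1	hypothetical
SfsA	MalQ	C1	hypothetical
DmlR	YeaT	C1	hypothetical
LgoR	yjjM	C1	hypothetical
YebK	HexR	C1	hypothetical
GalR		C2	strong
LrhA		C2	strong
NarP		C2	strong
RelE		C2	strong
RelB		C2	strong
PuuR		C2	strong
MqsA		C2	strong
LexA		C2	strong
McbR	YncC	C2	strong
SoxR		C2	strong
YefM		C2	strong
GlcC		C2	weak
Hha		C2	weak
MalI		C2	weak
MntR		C2	weak
NsrR		C2	weak
UidR		C2	weak
YdjF		C2	hypothetical
YeeY		C2	hypothetical
YgjM	HigA	C2	hypothetical
YgiT		C2	hypothetical
YjgJ		C2	hypothetical
AlaS		C3	strong
ArgR		C3	strong
BaeR		C3	strong
CpxR		C3	strong
CysB		C3	strong
FruR		C3	strong
NhaR		C3	strong
NikR		C3	strong
NrdR		C3	strong
PepA		C3	strong
PurR		C3	strong
SdiA		C3	strong
TreR		C3	strong
TrpR		C3	strong
TyrR		C3	strong
UxuR		C3	strong
YehT		C3	strong
YjiE	HypT	C3	strong
YqhC		C3	strong
AllR		C3	weak
AppY		C3	weak
BglJ		C3	weak
DeoR		C3	weak
EbgR		C3	weak
FabR		C3	weak
IdnR		C3	weak
LacI		C3	weak
UhpA		C3	weak
YcaN		C3	hypothetical
YdiA	PpsR	C3	hypothetical
YfeR		C3	hypothetical
YgbI		C3	hypothetical
YggD	FumE	C3	hypothetical
YhaJ		C3	hypothetical
YidZ		C3	hypothetical
Ada		C4	strong
CadC		C4	strong
ChbR		C4	strong
GlpR		C4	strong
DpiA		C4	strong
IhfB		C4	strong
HipB		C4	strong
GlrR	YfhA	C4	strong
PhoB		C4	strong
RutR		C4	strong
SlyA		C4	strong
TtdR		C4	strong
YdeO		C4	strong
Crl		C4	weak
CreB		C4	weak
DhaR		C4	weak
IlvY		C4	weak
PerR		C4	weak
SfsB		C4	weak
DicC		C4	hypothetical	noted_regulated_by_DicA
UNNAMED_C4		C4	hypothetical	unnamed_in_source_regulated_by_RcsB-BglJ
YbcL		C4	hypothetical
YbcM		C4	hypothetical
YbeF		C4	hypothetical
YbhD		C4	hypothetical
YdaS		C4	hypothetical
YddM		C4	hypothetical
YnfL		C4	hypothetical
YdhB		C4	hypothetical
YfhH		C4	hypothetical
YqeH		C4	hypothetical
YhjB		C4	hypothetical
YjhI		C4	hypothetical
YjjQ		C4	hypothetical
YjjJ		C4	hypothetical
CaiF		C5	strong
Cbl		C5	strong
CytR		C5	strong
FlhDC		C5	strong
Hns		C5	strong
HupA		C5	strong
HupB		C5	strong
IhfA		C5	strong
Lrp		C5	strong
NarL		C5	strong
GlnG		C5	strong
StpA		C5	strong
CsiR		C5	weak
EutR		C5	weak
MalT		C5	weak
OgrK		C5	hypothetical
YpdC		C5	hypothetical
YphH		C5	hypothetical
PLACEHOLDER_C5_1		C5		missing_in_extraction
CspA		C6	strong
MarA		C6	strong
UlaR		C6	strong
ComR	YcfQ	C6	strong
MarR		C6	weak
NemR	YdhM	C6	weak
CspH		C6	hypothetical
CspG		C6	hypothetical
YdfH		C6	hypothetical
YbaO		C6	hypothetical
AidB		C7	strong
GadE		C7	strong
PutA		C7	strong
BolA		C7	weak
LldR		C7	weak
CspD		C7	hypothetical
DctR		C7	hypothetical
YhjC		C7	hypothetical
YiaG		C7	hypothetical
YjdC		C7	hypothetical
AgaR		C8	strong
DicA		C8	strong
ArgP		C8	strong
EvgA		C8	strong
ExuR		C8	strong
FadR		C8	strong
FNR		C8	strong
Fur		C8	strong
IscR		C8	strong
GadW		C8	strong
NagC		C8	strong
NanR		C8	strong
PdhR		C8	strong
Rob		C8	strong
RstA		C8	strong
UvrY		C8	strong
YcgE	BluR	C8	strong
MlrA		C8	strong
GcvA		C8	weak
GntR		C8	weak
KdgR		C8	weak
YbaQ		C8	hypothetical
YciT	DeoT	C8	hypothetical
YfgA	RodZ	C8	hypothetical
PLACEHOLDER_C8_1		C8		missing_in_extraction
AdiY		C9	strong
ArcA		C9	strong
CueR		C9	strong
HdfR		C9	strong
LeuO		C9	strong
Nac		C9	strong
OmpR		C9	strong
OxyR		C9	strong
PhoP		C9	strong
PgrR	YcjZ	C9	strong
PspF		C9	strong	listed_twice_in_source_strong_and_weak
RcsA		C9	strong
RcsB		C9	strong
SoxS		C9	strong
YqjI		C9	strong
YeaM	NimR	C9	strong
AsnC		C9	weak
BetI		C9	weak
DsdC		C9	weak
LysR		C9	weak
PspC		C9	weak
YfaX	RhmR	C9	weak
YafC		C9	hypothetical
YbiH		C9	hypothetical
YeiE		C9	hypothetical
YieP		C9	hypothetical
YtfH		C9	hypothetical
YijO		C9	hypothetical
AtoC		C10	strong
Crp		C10	strong
CusR		C10	strong
DcuR		C10	strong
FhlA		C10	strong
Fis		C10	strong
KdpE		C10	strong
MprA		C10	strong
SgrR		C10	strong
RhaS		C10	strong
XylR		C10	strong
AllS		C10	weak
AlpA		C10	weak
ArsR		C10	weak
EnvR		C10	weak
EnvY		C10	weak
HycA		C10	weak
NadR		C10	weak
GutM		C10	weak
HyfR		C10	weak
PhnF		C10	weak
RbsR		C10	weak
RpiR	AlsR	C10	weak
RtcR		C10	weak
TdcR		C10	weak
YbdO		C10	hypothetical
CspE		C10	hypothetical
YmfL		C10	hypothetical
YdiP		C10	hypothetical
YqeI		C10	hypothetical
YgeH		C10	hypothetical
YidL		C10	hypothetical
YidP		C10	hypothetical
FrvR		C10	hypothetical
FimZ	YbcA	C10	hypothetical
SgcR	YjhJ	C10	hypothetical
SlmA	YicB	C10	hypothetical
DgoR	YidW	C10	hypothetical
AcrR		C11	strong
IclR		C11	strong
ModE		C11	strong
RcnR		C11	strong
TorR		C11	strong
YdcN		C11	strong
YedW		C11	strong
YegW		C11	strong
RcdA	YbjK	C11	strong
YahA	PdeL	C11	strong
Cnu		C11	weak
YagI		C11	hypothetical
YbfE		C11	hypothetical
CspI		C11	hypothetical
CspB		C11	hypothetical
CspF		C11	hypothetical
BirA		C12	strong
BasR		C12	strong
CynR		C12	strong
MetR		C12	strong
MngR		C12	strong
MurR	YfeT	C12	strong
PaaX		C12	strong
AscG		C12	weak
FrlR	yhfR	C12	weak
NorR		C12	weak
XapR		C12	weak
MazE		C12	weak
YafN		C12	hypothetical
YcjW		C12	hypothetical
YdcQ		C12	hypothetical
YdcR		C12	hypothetical
YeiI		C12	hypothetical
YfiE		C12	hypothetical
YiaU		C12	hypothetical
YihW		C12	hypothetical
YjhU		C12	hypothetical
YjiR		C12	hypothetical
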