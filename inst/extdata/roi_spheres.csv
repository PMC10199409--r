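region,hemisphere,x,y,z,size_voxels
OFA,Left,-33,-88,-10,49
OFA,Right,30,-91,-10,65
FFA,Left,-39,-46,-22,30
FFA,Right,39,17,23,44
pSTS,Left,-48,-49,14,54
pSTS,Right,48,-55,14,71
Precuneus,Medial,3,-52,29,81
IFG,Left,-36,20,26,38
IFG,Right,39,17,23,44
ATL,Left,-60,-7,-19,69
ATL,Right,57,-7,-19,81
Amygdala,Left,-21,-10,-13,62
Amygdala,Right,21,-7,-16,59
dmPFC,Medial,6,59,23,59
vmPFC,Medial,3,50,-19,66
OFC,Left,33,35,-13,58
OFC,Right,-33,35,-13,27
ATFP,Left,33,-10,-40,39
ATFP,Right,-36,-10,-34,24
AG,Left,-48,-67,35,68
AG,Right,42,-64,35,57
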