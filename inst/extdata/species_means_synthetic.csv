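species,mean_d2hf,sd_d2hf,presumed_molt_origin
ALFL,-51,25,nonlocal
AMRE,-140,10,local
CAWA,-146,11,local
CCSP,-152,12,local
CEDW,-72,28,nonlocal
CHSP,-97,20,nonlocal
COYE,-138,9,local
LEFL,-60,26,nonlocal
LISP,-148,13,local
MAWA,-141,8,local
MOWA,-151,4,local
YRWA,-137,12,local
OVEN,-144,10,local
REVI,-85,24,nonlocal
SAVS,-162,6,local
SOSP,-135,22,local
SWTH,-127,14,local
TEWA,-142,11,local
TRES,-66,30,nonlocal
WTSP,-139,15,local
YEWA,-147,9,local
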