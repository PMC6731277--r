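pam_suffix	weight
GG	1
AG	0.26
GA	0.07
AA	0
AC	0
AT	0
CA	0
CC	0
CG	0
CT	0
GC	0
GT	0
TA	0
TC	0
TG	0
TT	0
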