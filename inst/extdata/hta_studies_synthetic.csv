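study_id,ref,comp,loghr_os,se_os,loghr_pfs,se_pfs
CCI-NOV22,P,M+P,-0.1800,0.1687,-0.6000,0.1712
CALGB 9182,P,M+P,-0.0500,0.1376,-0.3500,0.1396
Berry 2002,P,M+P,-0.1024,0.1955,-0.4274,0.1983
TAX 327,M+P,D+P,-0.2744,0.1051,,
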