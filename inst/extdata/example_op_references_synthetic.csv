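membrane,species,exp_label,abs_SCH,segment
SYN_BILAYER,SYN,C12,0.44,headgroup
SYN_BILAYER,SYN,C22,0.40,sn-2
SYN_BILAYER,SYN,C23,0.35,sn-2
SYN_BILAYER,SYN,C24,0.30,sn-2
SYN_BILAYER,SYN,C25,0.24,sn-2
SYN_BILAYER,SYN,C32,0.42,sn-1
SYN_BILAYER,SYN,C33,0.38,sn-1
SYN_BILAYER,SYN,C34,0.33,sn-1
SYN_BILAYER,SYN,C35,0.28,sn-1
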