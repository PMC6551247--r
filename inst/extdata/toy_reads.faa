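>toy_read1
AQMPKDSCKRYPFTKIWRCK
>toy_read2
DSCKRYPFTKIWRCKCSNKN
>toy_read3
YPFTKIWRCKCSNKNNIDGW
>toy_read4
IWRCKCSNKNNIDGWRMHKC
>toy_read5
CSNKNNIDGWRMHKCHMWHS
>toy_read6
NIDGWRMHKCHMWHSEWCCL
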