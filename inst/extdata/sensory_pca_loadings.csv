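attribute,PC1,PC2,PC3
slippery,0.3692,0.5590,0.3267
soft,-0.3365,0.4593,-0.4970
rough,-0.5443,0.2214,0.3890
thick,-0.0707,0.1564,0.6656
greasy,0.5853,-0.1999,0.0710
pleasant,0.3265,0.6026,-0.2164
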