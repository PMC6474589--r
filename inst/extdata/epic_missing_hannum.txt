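# Hannum-clock CpGs (6 of 71) absent from the Illumina MethylationEPIC
# (850k) manifest relative to the 450k design.
cg24079702
cg07927379
cg21139312
cg14361627
cg18473521
cg09651136
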