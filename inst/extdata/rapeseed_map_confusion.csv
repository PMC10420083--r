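class,NOR,OR
NOR,27418,2226
OR,4163,21249
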