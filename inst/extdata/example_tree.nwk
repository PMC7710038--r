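((A:1.5,B:1.5)E:1,(C:1.5,D:1.5)F:1)G;
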