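((((S45,S48),S38),(S56,S57)),((S49,S63),((S34,S44),(S47,S54))));
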