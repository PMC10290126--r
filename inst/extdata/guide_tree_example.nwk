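(((((Ehux,Goce)Gephyrocapsa,Igal)Isochrysidales,(Cbra,Saps)Coccolithales)Calcihaptophycidae,(Chry,Pavl)OtherHaptophytes)Haptophyta,(Tpse,Ptri)Outgroup)Root;
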