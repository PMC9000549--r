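>S1_synthetic mildly acidic transmembrane segment (synthetic stand-in, not the crystallographic sequence)
ALVDLLAVLKDALLILAGLAVLAL
>S2_synthetic near-neutral transmembrane segment (synthetic stand-in)
LAVDLLAHLGVLLKALLVALGALL
>S3_synthetic acidic transmembrane segment (synthetic stand-in)
ALVDLLEGLADVLLELGALAVLAL
>S4_synthetic arginine-rich voltage-sensing segment (synthetic stand-in)
FLVRLLAGLLRALAVLLRGALVML
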