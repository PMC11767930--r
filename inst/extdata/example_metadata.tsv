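sample	subject	group
s01	S1	case
s02	S1	case
s03	S2	case
s04	S2	case
s05	S3	control
s06	S3	control
s07	S4	control
s08	S4	control
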