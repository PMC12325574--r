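very
really
so
extremely
totally
absolutely
definitely
truly
deeply
incredibly
especially
seriously
completely
utterly
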