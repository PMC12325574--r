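not
never
no
neither
nor
cannot
can't
don't
won't
didn't
isn't
wasn't
aren't
doesn't
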