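no
not
never
nothing
nobody
none
neither
nor
can't
don't
won't
didn't
isn't
wasn't
aren't
doesn't
couldn't
shouldn't
wouldn't
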