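# Transmembrane-domain boundaries of bovine rhodopsin (reference
# coordinates, closed intervals) — the community coordinate frame for
# opsin position numbering. Edit to taste; the package treats these as
# configuration, not constants.
TMD1 = 37-61
TMD2 = 74-96
TMD3 = 111-133
TMD4 = 153-173
TMD5 = 203-224
TMD6 = 253-274
TMD7 = 287-308
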