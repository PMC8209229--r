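# Starter list of curated FVIII binding-site residues (legacy mature
# numbering). INCOMPLETE by design: it carries only a handful of
# well-established FIXa-interface residues as a template; supply your own
# curated file (same columns) for a full binding-site analysis.
partner	chain	position	source
FIXa	A	557	a2-region FIXa interface
FIXa	A	562	a2-region FIXa interface
FIXa	A	568	a2-region FIXa interface
FIXa	A	712	a2-region FIXa interface
FIXa	A	713	a2-region FIXa interface
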