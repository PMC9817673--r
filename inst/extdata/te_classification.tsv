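pattern	te_class
^Simple_repeat	NonTE
^Low_complexity	NonTE
^Satellite	NonTE
^rRNA	NonTE
^tRNA	NonTE
^snRNA	NonTE
^scRNA	NonTE
^srpRNA	NonTE
^ARTEFACT	NonTE
Penelope	nonLTR
non-LTR	nonLTR
^DNA	DNA
^RC	DNA
^LINE	LINE
^SINE	SINE
^LTR	LTR
^Retroposon	Retro
^Retro	Retro
^Unknown	Unclear
^Unspecified	Unclear
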