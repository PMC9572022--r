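name	action
heme	canonicalize
hemin	canonicalize
hematin	canonicalize
heme arginate	exclude
heme-albumin	exclude
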