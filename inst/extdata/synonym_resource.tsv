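# word	class	relation	alternative
# relation: synonym = same synset; similar = one similar-to link away
elevated	adjective	synonym	raised
raised	adjective	synonym	elevated
raised	adjective	similar	increased
increased	adjective	similar	raised
increasing	adjective	synonym	increased
reduced	adjective	synonym	decreased
decreased	adjective	synonym	reduced
decreased	adjective	similar	worsening
worsening	adjective	similar	decreased
reduced	adjective	similar	depressed
depressed	adjective	similar	reduced
high	adjective	synonym	heightened
heightened	adjective	synonym	high
enlarged	adjective	synonym	dilated
dilated	adjective	synonym	enlarged
edema	noun	synonym	swelling
swelling	noun	synonym	edema
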