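>RHO_synthetic
MSGSSSGSSGSGSGSGSGSSGGSGSAAAMMAAAMMMMAMMMAAAAMSGGGGGGSGSGGSGSMAAAMAMAA
AMMMAAMMMAMMGSGSGGSGSGGGGGSMAMMAMAAAAAMMAMAAMMMMGGGSGGGGSSSSGSSMAAMMMA
MAMAMAMAAMAAMMGGGSGGSSSSSGGGSAMAAAAAMAAMMMAMAMMAAMSSSSGGSGSSGSSSSMAAMM
AAMAMAAMMMAAAAAASGGGSGGGSGSSGGGMMAAMAAMAMAAAAAAAMMAMGSSGGGGSGGGSSGSSSS
GSSGSSGSSGSSSSGGGGSGSG
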