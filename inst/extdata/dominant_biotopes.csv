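biotope,category
macroalgae,organic
ranunculus,organic
sparganium,organic
gravel,mineralogical
sand,mineralogical
gravel_sand,mineralogical
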