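acute phase reactions
pattern recognition
antigen processing and regulators
complement system
inflammatory cytokines and receptors
adapters, effectors and signal transducers
innate immune cells related
T/B cell antigen activation
other genes related to immune response
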