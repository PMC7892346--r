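# synthetic example of a splicing-enhancer hexamer list (one 6-mer per line)
GAAGAA
TGAAGA
AGAAGT
GGAAGG
CAGAAG
GAAGGA
TCAAGG
AAGAAC
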