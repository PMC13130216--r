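# Generic and brand names recognised for each study drug.
cyclosporine:
  - cyclosporine
  - ciclosporin
  - cyclosporin
  - neoral
  - sandimmune
  - gengraf
tacrolimus:
  - tacrolimus
  - prograf
  - advagraf
  - astagraf
  - envarsus
  - protopic
voclosporin:
  - voclosporin
  - lupkynis
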