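# Exact coefficient values used by the quality metrics (see iqa_coefficients()).
uiqm:
  uicm: 0.0282
  uism: 0.2953
  uiconm: 3.5753
uicm:
  mu: -0.0268
  sigma: 0.1586
  trim: 0.1
uciqe:
  sigma_chroma: 0.4680
  con_luminance: 0.2745
  mu_saturation: 0.2576
ccf:
  colorfulness: 0.17593
  contrast: 0.61759
  clarity: 0.33988
block_size: 10
luma:
  r: 0.299
  g: 0.587
  b: 0.114
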