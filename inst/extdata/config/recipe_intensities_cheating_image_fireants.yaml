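# Linear rules deriving each tissue class's synthetic mean intensity from
# the robust medians of the seven structures the coarse segmentation
# delineates reliably (cerebral/cerebellar gray and white matter,
# brainstem, thalamus, pallidum). Weights may deviate from sum one to
# darken or brighten a class.
cerebral white matter:
  cerebral white matter: 1.0
cerebral gray matter:
  cerebral gray matter: 1.0
cerebellar white matter:
  cerebellar white matter: 1.0
cerebellar cortex:
  cerebellar gray matter: 1.0
caudate:
  cerebral gray matter: 1.0
putamen:
  cerebral gray matter: 0.9
  cerebral white matter: 0.1
pallidum:
  pallidum: 1.0
lateral thalamus:
  thalamus: 0.7
  cerebral white matter: 0.3
medial thalamus:
  thalamus: 0.85
  cerebral gray matter: 0.15
red nucleus:
  cerebral white matter: 0.6
  cerebral gray matter: 0.4
compact brainstem white matter:
  brainstem: 0.5
  cerebral white matter: 0.5
diffuse brainstem white matter:
  brainstem: 1.0
hypothalamus:
  cerebral gray matter: 1.0
mammillary bodies:
  cerebral white matter: 0.5
  cerebral gray matter: 0.5
dentate nucleus of the cerebellum:
  cerebellar white matter: 0.6
  cerebellar gray matter: 0.4
hippocampal white matter:
  cerebral white matter: 0.7
  cerebral gray matter: 0.3
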