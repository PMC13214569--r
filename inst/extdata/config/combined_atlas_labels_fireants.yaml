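# Default grouping of atlas ROIs into tissue classes sharing an intensity
# model. Label ids are atlas-specific: fill each list with the ROI ids of
# the atlas in use (the phantom generator writes its own version of this
# file). The class set itself is the default 16-class grouping.
cerebral white matter: []
cerebral gray matter: []
cerebellar white matter: []
cerebellar cortex: []
caudate: []
putamen: []
pallidum: []
lateral thalamus: []
medial thalamus: []
red nucleus: []
compact brainstem white matter: []
diffuse brainstem white matter: []
hypothalamus: []
mammillary bodies: []
dentate nucleus of the cerebellum: []
hippocampal white matter: []
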