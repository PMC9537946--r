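# Packaged 12-ROI network definitions.  Each region is instantiated once per
# hemisphere (left before right).  `parcels` lists the cortical atlas parcels
# (HCP multi-modal parcellation v1.0) or subcortical segmentation indices
# (FSL FIRST: 17/53 hippocampus, 18/54 amygdala, 26/58 accumbens) that were
# averaged to form each ROI upstream; they are metadata only — this package
# consumes ROI-mean time series, not voxel or surface data.
dmn:
  name: DMN
  regions:
    - code: PCC
      long_name: posterior cingulate cortex
      parcels: [7m, 31pd, 31pv, d23ab, v23ab, 31a, 23d, POS1]
    - code: mPFC
      long_name: medial prefrontal cortex
      parcels: [s32, a24, p32, 10r, 10d, 9m]
    - code: IPC
      long_name: inferior parietal cortex
      parcels: [PGi, PGs, PFm]
    - code: MTG
      long_name: middle temporal gyrus
      parcels: [TE1a, TE1p, TE2a, TE1m]
    - code: DLPFC
      long_name: dorsolateral prefrontal cortex
      parcels: [8Av, 8C]
    - code: HC
      long_name: hippocampus
      parcels: ['17', '53']
fln:
  name: FLN
  regions:
    - code: OFC
      long_name: orbitofrontal cortex
      parcels: [11l, 13l, 47m, 47s, 10v, OFC, 10pp]
    - code: mPFC
      long_name: medial prefrontal cortex
      parcels: [s32, a24, p32, 10r, 10d, 9m]
    - code: ACC
      long_name: anterior cingulate cortex
      parcels: [p24, a24pr, p24pr]
    - code: AMG
      long_name: amygdala
      parcels: ['18', '54']
    - code: NAcc
      long_name: nucleus accumbens
      parcels: ['26', '58']
    - code: HC
      long_name: hippocampus
      parcels: ['17', '53']
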