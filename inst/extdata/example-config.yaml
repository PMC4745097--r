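# Example widecal pipeline configuration (simulate mode).
# Any omitted key falls back to the package default; unknown keys are
# rejected. See ?simParams, ?registrationParams, ?detectionParams,
# ?mergeParams, ?behaviorParams, ?analysisParams, ?spatialParams.
seed: 1
sim:
  frameHeight: 256
  frameWidth: 256
  nFrames: 1000
  nCells: 20
registration:
  filterSigma: 32
  maxShift: 25
detection:
  z0: 1.5
merge:
  maxIou: 0.3
behavior:
  thresholdK: 4
analysis:
  alpha: 0.05
spatial:
  nResamples: 500
writeIntermediates: true
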