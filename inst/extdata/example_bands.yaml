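# user-defined fixed saturation band, plus a retuned cap for the
# peak-tracking metric
green:
  lo: 500
  hi: 570
S3Sc:
  mode: peak_tracking
  half_width: 50
  cap: 600
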