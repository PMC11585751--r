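# Example ki67pi run configuration. Any subset of keys may be given;
# omitted keys keep the package defaults, unknown keys are rejected.
mpp: 0.5
seed: 1
stains:
  hematoxylin: [0.650, 0.704, 0.286]
  dab: [0.269, 0.568, 0.778]
segmentation:
  threshold_method: otsu   # or "fixed" with fixed_threshold (OD units)
  min_distance_px: 7       # minimum seed separation
  min_height: 0.2          # minimum normalised distance-map peak
  min_area_um2: 10         # debris gate
  max_area_um2: 400        # clump gate
  connectivity: 8
classification:
  dab_threshold: 0.15      # mean DAB OD for a positive call; 0 = any intensity
  statistic: mean          # or "median"
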