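# Operating point for the 112-band (1/2-binned) VNIR seaweed line.
# Band indices are 1-based into the binned cube.
visible:
  range_nm: [400, 750]
  pair: [26, 63]          # ~532 nm and ~732 nm
  intervals:
    seaweed: [60, 80]
    belt: [20, 45]
nir:
  range_nm: [750, 1000]
  pair: [68, 93]          # ~759 nm and ~897 nm
  intervals:
    seaweed: [-30, -5]
    belt: [5, 25]
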