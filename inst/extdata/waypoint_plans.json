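{
  "version": "1.0",
  "notes": "Schematic letter-shaped waypoint plans, ~50 um extent, coordinates in um. Synthetic geometries: vertices trace each letter as an ordered polyline.",
  "plans": {
    "A": [[0, 0], [15, 50], [30, 0], [22.5, 25], [7.5, 25]],
    "R": [[0, 0], [0, 50], [20, 50], [26, 42], [20, 32], [0, 30], [26, 0]],
    "S": [[26, 46], [10, 50], [0, 40], [10, 30], [20, 22], [26, 12], [16, 0], [0, 4]],
    "M": [[0, 0], [0, 50], [15, 25], [30, 50], [30, 0]],
    "U": [[0, 50], [0, 14], [8, 0], [22, 0], [30, 14], [30, 50]]
  }
}
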