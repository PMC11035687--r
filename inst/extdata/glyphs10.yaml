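# Frozen 10-class stroke-glyph specification (digit-like synthetic glyphs).
# Coordinates are in the unit square with y pointing down; angles in degrees.
# Class geometry encodes the similarity structure the satiation protocols
# rely on: class "7" shares a long near-vertical stroke with class "1",
# class "9" shares a shorter, off-centre one, class "3" shares none.
version: 1
image_size: 28
thickness: 0.04
aa: 0.02
noise_sd: 0.05
jitter_sd: 0.05
seed: 42
classes:
  - name: "0"
    strokes:
      - {type: arc, cx: 0.50, cy: 0.50, rx: 0.18, ry: 0.28, from: 0, to: 360}
  - name: "1"
    strokes:
      - {type: line, x1: 0.50, y1: 0.16, x2: 0.50, y2: 0.84}
  - name: "2"
    strokes:
      - {type: arc, cx: 0.50, cy: 0.34, rx: 0.16, ry: 0.16, from: 180, to: 360}
      - {type: line, x1: 0.66, y1: 0.34, x2: 0.34, y2: 0.84}
      - {type: line, x1: 0.34, y1: 0.84, x2: 0.70, y2: 0.84}
  - name: "3"
    strokes:
      - {type: arc, cx: 0.55, cy: 0.33, rx: 0.13, ry: 0.15, from: -140, to: 90}
      - {type: arc, cx: 0.55, cy: 0.67, rx: 0.14, ry: 0.17, from: -90, to: 140}
  - name: "4"
    strokes:
      - {type: line, x1: 0.58, y1: 0.16, x2: 0.30, y2: 0.55}
      - {type: line, x1: 0.30, y1: 0.55, x2: 0.75, y2: 0.55}
      - {type: line, x1: 0.62, y1: 0.30, x2: 0.62, y2: 0.84}
  - name: "5"
    strokes:
      - {type: line, x1: 0.68, y1: 0.18, x2: 0.34, y2: 0.18}
      - {type: line, x1: 0.34, y1: 0.18, x2: 0.34, y2: 0.48}
      - {type: arc, cx: 0.48, cy: 0.64, rx: 0.18, ry: 0.18, from: -100, to: 130}
  - name: "6"
    strokes:
      - {type: line, x1: 0.60, y1: 0.16, x2: 0.38, y2: 0.50}
      - {type: arc, cx: 0.50, cy: 0.64, rx: 0.16, ry: 0.17, from: 0, to: 360}
  - name: "7"
    strokes:
      - {type: line, x1: 0.32, y1: 0.18, x2: 0.64, y2: 0.18}
      - {type: line, x1: 0.58, y1: 0.18, x2: 0.48, y2: 0.84}
  - name: "8"
    strokes:
      - {type: arc, cx: 0.50, cy: 0.32, rx: 0.13, ry: 0.14, from: 0, to: 360}
      - {type: arc, cx: 0.50, cy: 0.66, rx: 0.16, ry: 0.17, from: 0, to: 360}
  - name: "9"
    strokes:
      - {type: arc, cx: 0.47, cy: 0.31, rx: 0.13, ry: 0.13, from: 0, to: 360}
      - {type: line, x1: 0.58, y1: 0.31, x2: 0.52, y2: 0.84}
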