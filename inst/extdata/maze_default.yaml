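# Six-patch trapezoid maze: 70/40/70 cm isosceles trapezoid outline,
# six 13-cm circular patches, 2.5-cm-wide channels, all lengths in metres.
# Patch positions and channel network are the bundled layout choice.
units: m
wall_margin: 0.01
arena:
  - [0.00, 0.0000]
  - [0.70, 0.0000]
  - [0.55, 0.6837]
  - [0.15, 0.6837]
patches:
  - {id: "1", cx: 0.15, cy: 0.12, diameter: 0.13, resource_g: 1.0}
  - {id: "2", cx: 0.35, cy: 0.12, diameter: 0.13, resource_g: 0.0}
  - {id: "3", cx: 0.55, cy: 0.12, diameter: 0.13, resource_g: 0.0}
  - {id: "4", cx: 0.25, cy: 0.38, diameter: 0.13, resource_g: 0.0}
  - {id: "5", cx: 0.45, cy: 0.38, diameter: 0.13, resource_g: 0.5}
  - {id: "6", cx: 0.35, cy: 0.60, diameter: 0.13, resource_g: 0.0}
channels:
  - {id: "c12", from: "1", to: "2", width: 0.025}
  - {id: "c23", from: "2", to: "3", width: 0.025}
  - {id: "c14", from: "1", to: "4", width: 0.025}
  - {id: "c25", from: "2", to: "5", width: 0.025}
  - {id: "c35", from: "3", to: "5", width: 0.025}
  - {id: "c45", from: "4", to: "5", width: 0.025}
  - {id: "c46", from: "4", to: "6", width: 0.025}
  - {id: "c56", from: "5", to: "6", width: 0.025}
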