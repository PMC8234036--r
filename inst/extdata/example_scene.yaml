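# A small synthetic vineyard scene: one six-bird flock crossing the view,
# a near-lens insect, and a patch of quivering foliage.
width: 120
height: 90
n_frames: 12
seed: 7
background_level: 60
noise_sd: 2
leaf_quiver:
  regions:
    - [80, 60, 110, 85]
  amplitude: 12
  period: 1
objects:
  - kind: flock
    x: 20
    "y": 30
    vx: 2
    vy: 0
    members: 6
  - kind: bug
    x: 60
    "y": 10
    step_sd: 4
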