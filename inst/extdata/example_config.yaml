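# Example session configuration with every default spelled out.
# The camera block describes the wearable view camera actually used for
# the recording; resolution and viewing angles are hardware properties
# and must be set per device.
camera:
  width: 640
  height: 480
  fov_x: 80.0        # horizontal viewing angle, deg
  fov_y: 60.0        # vertical viewing angle, deg
markers:             # searched in id order; left-to-right on the windshield
  - id: 1
    shape: triangle_up
    template: templates/marker1.png
  - id: 2
    shape: circle
    template: templates/marker2.png
  - id: 3
    shape: triangle_down
    template: templates/marker3.png
  - id: 4            # off-screen while facing forward; reference extrapolated
    shape: star
    template: templates/marker4.png
layout:
  alpha: 2.0         # Marker2-Marker3 spacing : Marker3-Marker4 spacing
  beta: 3.0
frame_rate: 10       # view-camera frames per second
similarity_threshold: 0.70   # NCC acceptance threshold, [0, 1]
search:
  margin: 48         # px, tracking-window half-width
  extension_gain: 1.5  # window growth per px of inter-frame motion
bin_width: 5         # deg, gaze histogram bins
range_threshold: 0.05  # fraction of the peak marginal count
calibration:
  n_frames: 50       # forward-facing frames used for reference positions
# zones: omit to use the default nine-zone map (see default_zone_map())
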