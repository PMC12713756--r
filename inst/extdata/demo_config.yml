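# Demo pipeline configuration.
# Every stochastic stage derives its RNG stream from `seed`.
seed: 1
out_dir: gastruloidr-demo
pixel_size_um: 0.65

colonies:
  replicates: 2          # synthetic colonies per pattern condition
  density: 600           # cells/mm^2 (kept small for a fast demo)
  radius_um: 250
  patterns: [ring, uniform]
  amplitude: 100         # BRA field peak over background, a.u.
  background: 10

segmentation:
  background_radius_um: 20
  dilation_radius_um: 1
  min_area_um2: 30
  max_area_um2: 200
  min_circularity: 0.6

profile:
  bin_um: 10
  channel: BRA

pfi:
  dialect: screen        # edge band 10-40 um from the colony edge

screen:
  delays: [0, 6, 12, 18, 24, 30, 36, 42]
  durations: [6, 12, 18, 24, 30, 36, 42, 48]
  replicates: 5
  rho0: 1500             # seeding density, cells/mm^2
  doubling_time: 24      # h
  rho_star: 2400         # competence-peak density, cells/mm^2
  kernel_sd: 500
  bmp_gain: 2
  noise_sd: 0.5
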