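# Shared small synthetic scenes used across test files.

# one 8 Hz patch, 200 fps; small field keeps the FFT suite fast
small_cbf_scene <- function(n_frames = 512L, freq = 8, seed = 2L) {
  cilia_scene(field_size_px = c(96L, 96L), frame_rate_hz = 200,
              n_frames = n_frames,
              patches = list(list(center = c(40, 40), radius_px = 12,
                                  frequency_hz = freq, phase_rad = 0.3,
                                  amplitude = 20)),
              noise_sd = 2, seed = seed)
}

# labelled mixed benchmark at the generator's default separation
mixed_flow_scene <- function(n_per_class = 100L, seed = 5L, ...) {
  flow_scene(n_mcc = n_per_class, n_background = n_per_class, seed = seed, ...)
}

# build a track_set directly from a displacement list:
# each element c(x0, y0, dx, dy) becomes a 2-node track
tracks_from_displacements <- function(disp, field = c(100, 100), fps = 30) {
  df <- do.call(rbind, lapply(seq_along(disp), function(i) {
    d <- disp[[i]]
    data.frame(track_id = i, frame = 0:1,
               x_um = c(d[1], d[1] + d[3]), y_um = c(d[2], d[2] + d[4]))
  }))
  track_set(df, frame_rate_hz = fps, field_size_um = field)
}

# Calibrate the threshold classifier the way it is done at the bench: track
# rendered movies of a cell-free scene (pure background flow) and of strong
# directed MCC flow, label the recovered tracks by scene, and calibrate on
# those features. Recovered (not generated) tracks carry the detector's
# localization noise, which the thresholds must absorb.
calibrate_on_rendered <- function(seed, field = c(400, 400),
                                  kind = c("tree", "threshold")) {
  kind <- match.arg(kind)
  g <- channel_geometry(field)
  bg <- gen_bead_tracks(flow_scene(field_size_um = field, n_frames = 80L,
                                   n_mcc = 0L, n_background = 60L,
                                   min_track_frames = 80L, seed = seed))
  mc <- gen_bead_tracks(flow_scene(field_size_um = field, n_frames = 80L,
                                   n_mcc = 60L, n_background = 0L,
                                   mcc_speed_um_s = c(12, 3),
                                   min_track_frames = 80L, seed = seed + 1L))
  tb <- track_beads(render_bead_video(bg$tracks, pixel_size_um = 2,
                                      seed = seed + 2L),
                    max_disp_um = 6, min_track_len = 10)
  tm <- track_beads(render_bead_video(mc$tracks, pixel_size_um = 2,
                                      seed = seed + 3L),
                    max_disp_um = 6, min_track_len = 10)
  fb <- feature_table(tb, g)
  fm <- feature_table(tm, g)
  labels <- c(rep("background", nrow(fb)), rep("mcc", nrow(fm)))
  if (kind == "tree") train_tree(rbind(fb, fm), labels, seed = seed)
  else calibrate_thresholds(rbind(fb, fm), labels)
}

# trajectories at given angles (deg, 0 = inlet) with unit net displacement
tracks_at_angles <- function(angles_deg, geom = channel_geometry(c(100, 100))) {
  v <- mucoflow:::direction_to_vector(angles_deg, geom)
  tracks_from_displacements(
    lapply(seq_along(angles_deg), function(i) c(50, 50, v[i, 1], v[i, 2])),
    field = geom$field_size_um)
}
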