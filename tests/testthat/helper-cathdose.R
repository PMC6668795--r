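# shared fixtures, built in code

# the 10-year-old, 35 kg, DAP 683.13 cGy.cm2 reference patient
worked_example_summary <- function() {
  normalize_doses(tibble::tibble(
    procedure_id = "WE1", patient_id = "pat1", age = 10, sex = "male",
    height_cm = 139.8, weight_kg = 35, procedure_type = "Diagnostic",
    n_events = 1L, total_dap = 683.13, dap_frontal = 683.13,
    dap_lateral = 0, dap_fluoro = 683.13, dap_cine = 0,
    total_kerma_mgy = 95, fluoro_time_s = 600, cine_frames = 0L,
    is_biplane = TRUE
  ))
}

# a minimal canonical event row; override any field via ...
make_event <- function(...) {
  ev <- tibble::tibble(
    procedure_id = "P1", patient_id = "pat1", age = 5, sex = "female",
    height_cm = 109, weight_kg = 19, procedure_type = "Diagnostic",
    plane = "frontal", irradiation_type = "fluoroscopy",
    dap_cgycm2 = 100, kerma_mgy = 14, duration_s = 60, frame_count = 0,
    primary_angle = 0, secondary_angle = 0, source_isocenter_mm = 765,
    source_detector_mm = 1100, kvp = 80, filtration_cu_mm = 0.4
  )
  over <- list(...)
  for (nm in names(over)) ev[[nm]] <- over[[nm]]
  ev
}

make_events <- function(n, ...) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) make_event(...)))
}

# independent numeric oracle for the heart-to-skin distance: bisect on the
# elliptical-cylinder surface along the 3D ray
fsd_oracle <- function(a_mm, b_mm, primary, secondary, sad_mm,
                       tol = 1e-6) {
  p <- primary * pi / 180
  s <- secondary * pi / 180
  ux <- sin(p) * cos(s)
  uy <- cos(p) * cos(s)
  f <- function(t) ((t * ux) / a_mm)^2 + ((t * uy) / b_mm)^2 - 1
  lo <- 0
  hi <- max(a_mm, b_mm) / cos(s) + 1
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  sad_mm - (lo + hi) / 2
}

# scaled-phantom stub with explicit semi-axes (cm), heart on axis
phantom_stub <- function(lat_cm, ap_cm) {
  list(trunk_semi_axis_lat_cm = lat_cm, trunk_semi_axis_ap_cm = ap_cm,
       heart_offset_lat_cm = 0, heart_offset_ap_cm = 0)
}
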