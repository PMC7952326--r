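## Synthetic fixture generation: seeded chamber meshes, activation and
## voltage fields with known ground truth, and electrogram synthesis.
## These are first-class study generators used by the test-suite and the
## `synth` CLI subcommand; they emulate a mapped left atrium (ellipsoidal
## chamber with valve/vein cut-outs), not its physiology.

#' Chamber mesh specification
#'
#' @param radius base chamber radius in mm.
#' @param scale length-3 ellipsoid scale factors applied per axis.
#' @param subdiv icosphere subdivision level (>= 1); level s gives
#'   20 * 4^s triangles before cut-outs.
#' @param holes list of cut-outs, each `list(direction = unit vector,
#'   angular_radius = radians)`; defaults emulate a mitral valve plus four
#'   pulmonary vein ostia.
#' @param jitter_sd radial vertex jitter SD in mm (< 0.1 * radius).
#' @param seed RNG seed for the jitter.
#' @return An object of class `chamber_spec`.
#' @export
chamber_spec <- function(radius = 30, scale = c(1, 1, 1), subdiv = 3,
                         holes = default_holes(), jitter_sd = 0, seed = 1L) {
  if (subdiv < 1) stop_eam("subdiv must be >= 1", "eam_argument_error")
  if (jitter_sd >= 0.1 * radius)
    stop_eam("jitter_sd must be < 0.1 * radius", "eam_argument_error")
  check_holes(holes)
  structure(list(radius = radius, scale = scale, subdiv = subdiv,
                 holes = holes, jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "chamber_spec")
}

#' Default cut-outs: one valve plus four vein ostia
#' @return list of hole specifications.
#' @export
default_holes <- function() {
  veins <- list(c(0.45, 0.45, 1), c(-0.45, 0.45, 1), c(0.45, -0.45, 1),
                c(-0.45, -0.45, 1))
  c(list(list(direction = c(0, 0, -1), angular_radius = 0.45)),
    lapply(veins, function(d) list(direction = d / sqrt(sum(d^2)),
                                   angular_radius = 0.22)))
}

check_holes <- function(holes) {
  if (length(holes) < 2L) return(invisible(TRUE))
  for (i in seq_along(holes)) {
    holes[[i]]$direction <- holes[[i]]$direction / sqrt(sum(holes[[i]]$direction^2))
  }
  for (i in seq_len(length(holes) - 1L)) {
    for (j in (i + 1L):length(holes)) {
      ang <- acos(pmin(pmax(sum(holes[[i]]$direction * holes[[j]]$direction), -1), 1))
      if (ang <= holes[[i]]$angular_radius + holes[[j]]$angular_radius)
        stop_eam(sprintf("holes %d and %d overlap", i, j), "eam_argument_error")
    }
  }
  invisible(TRUE)
}

## unit icosphere at given subdivision level (vertices on the unit sphere)
icosphere <- function(subdiv) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edge_mid <- new.env(hash = TRUE, parent = emptyenv())
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- edge_mid[[key]]
      if (!is.null(m)) return(m)
      p <- (v[i, ] + v[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- matrix(p, 1, 3)
      edge_mid[[key]] <- nv
      nv
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf[(k - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  list(vertices = v, triangles = f)
}

#' Generate a chamber surface mesh
#'
#' Builds a subdivided icosphere, scales it to the requested ellipsoid,
#' applies seeded radial jitter and removes the triangles inside each
#' cut-out cone. The result is manifold-with-boundary with one free
#' boundary loop per hole.
#'
#' @param spec a [chamber_spec()].
#' @return An [eam_mesh()].
#' @export
make_chamber_mesh <- function(spec) {
  ico <- icosphere(spec$subdiv)
  dirs <- ico$vertices                       # unit directions, pre-jitter
  r <- spec$radius
  if (spec$jitter_sd > 0) {
    set.seed(spec$seed)
    r <- r + rnorm(nrow(dirs), 0, spec$jitter_sd)
  }
  v <- dirs * r
  v <- sweep(v, 2, spec$scale, "*")
  tri <- ico$triangles
  if (length(spec$holes)) {
    cen_dir <- (dirs[tri[, 1], ] + dirs[tri[, 2], ] + dirs[tri[, 3], ]) / 3
    cen_dir <- cen_dir / sqrt(rowSums(cen_dir^2))
    drop <- rep(FALSE, nrow(tri))
    for (h in spec$holes) {
      d <- h$direction / sqrt(sum(h$direction^2))
      ang <- acos(pmin(pmax(cen_dir %*% d, -1), 1))
      drop <- drop | (ang < h$angular_radius)
    }
    tri <- tri[!drop, , drop = FALSE]
  }
  keep <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(v)); remap[keep] <- seq_along(keep)
  eam_mesh(v[keep, , drop = FALSE],
           matrix(remap[tri], ncol = 3), validate = TRUE)
}

#' Activation wavefront specification
#'
#' @param mode `"planar"` (constant-velocity plane wave) or `"focal"`
#'   (radial spread from a source vertex at constant speed along the
#'   surface).
#' @param speed conduction speed in m/s (= mm/ms).
#' @param direction unit propagation direction (planar mode).
#' @param source_vertex 1-based source vertex index (focal mode).
#' @param t0 activation time offset in ms.
#' @return An object of class `wave_spec`.
#' @export
wave_spec <- function(mode = c("planar", "focal"), speed = 1,
                      direction = c(1, 0, 0), source_vertex = 1L, t0 = 0) {
  mode <- match.arg(mode)
  if (speed <= 0) stop_eam("speed must be > 0", "eam_argument_error")
  direction <- direction / sqrt(sum(direction^2))
  structure(list(mode = mode, speed = speed, direction = direction,
                 source_vertex = as.integer(source_vertex), t0 = t0),
            class = "wave_spec")
}

#' Simulate an activation field with ground truth
#'
#' Planar mode assigns `t(x) = t0 + n . (x - x_min) / v` (closed form, exact
#' linear field). Focal mode propagates along the mesh edge graph by
#' shortest paths (Dijkstra) from the source vertex, which slightly
#' overestimates the true geodesic distance; planar waves are therefore the
#' fixtures for exact conduction-velocity recovery.
#'
#' @param mesh an [eam_mesh()].
#' @param wave a [wave_spec()].
#' @return list with `lat` (per-vertex LAT, ms) and `truth` (true total
#'   activation time, earliest vertex, speed and wave description).
#' @export
simulate_activation <- function(mesh, wave) {
  v <- mesh$vertices
  if (wave$mode == "planar") {
    proj <- as.numeric(v %*% wave$direction)
    lat <- wave$t0 + (proj - min(proj)) / wave$speed
  } else {
    if (wave$source_vertex < 1L || wave$source_vertex > nrow(v))
      stop_eam("focal source vertex not on the mesh", "eam_argument_error")
    d <- geodesic_distances(mesh, wave$source_vertex)
    if (any(!is.finite(d)))
      stop_eam("mesh is disconnected: focal wave cannot reach all vertices",
               "eam_topology_error")
    lat <- wave$t0 + d / wave$speed
  }
  list(lat = lat,
       truth = list(tat = max(lat) - min(lat),
                    earliest_vertex = which.min(lat),
                    earliest_position = v[which.min(lat), ],
                    speed = wave$speed, wave = wave))
}

#' Simulate a bipolar voltage field with ground truth
#'
#' Vertices within the (edge-graph) geodesic radius of a patch centre take
#' the patch level; all other vertices take the background level. The truth
#' record reports, per patch and overall, the area of triangles fully
#' inside the low-voltage region and an exact below-threshold area of the
#' linearly interpolated field computed with an independent closed-form
#' order-statistic formula (see [tri_area_below_oracle()]).
#'
#' @param mesh an [eam_mesh()].
#' @param patches list of `list(center_vertex, radius, level)` with radius
#'   in mm and level in mV.
#' @param background background voltage in mV.
#' @param threshold threshold (mV) at which the truth areas are reported;
#'   default 0.5 mV, the conventional low-voltage cut-off.
#' @return list with `bip` (per-vertex voltage) and `truth` (patch vertex
#'   sets, full-triangle area and exact linear-field low-voltage area, cm^2).
#' @export
simulate_voltage_field <- function(mesh, patches = list(), background = 3,
                                   threshold = 0.5) {
  if (length(patches) && any(vapply(patches, function(p) p$level, 1) < 0))
    stop_eam("patch levels must be >= 0", "eam_argument_error")
  n <- nrow(mesh$vertices)
  bip <- rep(background, n)
  in_patch <- rep(FALSE, n)
  for (p in patches) {
    d <- geodesic_distances(mesh, p$center_vertex)
    sel <- d <= p$radius
    bip[sel] <- p$level
    in_patch <- in_patch | sel
  }
  tri <- mesh$triangles
  areas <- triangle_areas(mesh)
  full_inside <- in_patch[tri[, 1]] & in_patch[tri[, 2]] & in_patch[tri[, 3]]
  low_exact <- sum(tri_area_below_oracle(bip[tri[, 1]], bip[tri[, 2]],
                                         bip[tri[, 3]], threshold, areas))
  list(bip = bip,
       truth = list(patch_vertices = which(in_patch),
                    area_full_triangles_cm2 = sum(areas[full_inside]) / 100,
                    area_below_threshold_cm2 = low_exact / 100,
                    threshold = threshold, background = background))
}

#' Exact below-threshold triangle area (closed form)
#'
#' Independent oracle for sub-triangle low-voltage areas: for a linear
#' field with vertex values `v1,v2,v3` on a triangle of area `A`, the area
#' of the sub-region below `thr` has a closed form in the sorted values.
#' Used by the synthetic truth records and as a cross-check of the
#' polygon-clipping implementation in the voltage metrics.
#'
#' @param v1,v2,v3 vertex values (vectors).
#' @param thr threshold.
#' @param area triangle areas.
#' @return vector of sub-areas (same units as `area`).
#' @export
tri_area_below_oracle <- function(v1, v2, v3, thr, area) {
  m <- cbind(v1, v2, v3)
  s <- t(apply(m, 1, sort))
  out <- numeric(length(area))
  hi <- thr >= s[, 3]
  out[hi] <- area[hi]
  mid <- !hi & thr > s[, 2]
  out[mid] <- area[mid] *
    (1 - (s[mid, 3] - thr)^2 / ((s[mid, 3] - s[mid, 1]) * (s[mid, 3] - s[mid, 2])))
  lo <- !hi & !mid & thr > s[, 1]
  out[lo] <- area[lo] * (thr - s[lo, 1])^2 /
    ((s[lo, 2] - s[lo, 1]) * (s[lo, 3] - s[lo, 1]))
  out
}

#' Electrogram synthesis specification
#'
#' @param fs sampling frequency, Hz (>= 500).
#' @param n_samples trace length T in samples.
#' @param amplitude unipolar amplitude A in mV.
#' @param width deflection width tau in ms.
#' @param delay inter-electrode conduction delay in ms (distal leads
#'   proximal).
#' @param noise_sd additive Gaussian noise SD in mV.
#' @param seed RNG seed for the noise.
#' @return An object of class `egm_spec`.
#' @export
egm_spec <- function(fs = 1000, n_samples = 1000, amplitude = 1, width = 5,
                     delay = 2, noise_sd = 0, seed = 1L) {
  if (fs < 500) stop_eam("fs must be >= 500 Hz", "eam_argument_error")
  if (width <= 0) stop_eam("width must be > 0", "eam_argument_error")
  if (noise_sd < 0) stop_eam("noise_sd must be >= 0", "eam_argument_error")
  structure(list(fs = fs, n_samples = as.integer(n_samples),
                 amplitude = amplitude, width = width, delay = delay,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "egm_spec")
}

## Gaussian-derivative unipolar template: u(t) = -A ((t-t*)/tau) exp(-(t-t*)^2/(2 tau^2)).
## Its steepest negative slope is exactly at t*, the conventional LAT marker.
egm_template <- function(t_ms, t_star, amplitude, tau) {
  s <- (t_ms - t_star) / tau
  -amplitude * s * exp(-s^2 / 2)
}

#' Synthesize electrograms at sampled surface vertices
#'
#' For each sampled vertex with true activation time t*, the unipolar pair
#' is a Gaussian-derivative deflection at t* (distal) and t* + delay
#' (proximal); the bipolar trace is distal - proximal plus seeded Gaussian
#' noise. The activation annotation is placed at t* on the trace clock;
#' the reference trace is a fixed template at the reference annotation and
#' the window of interest is chosen to contain every annotation. The point
#' bipolar voltage is the peak-to-peak amplitude of the noiseless bipolar
#' trace.
#'
#' @param mesh an [eam_mesh()].
#' @param lat per-vertex LAT field (ms), e.g. from [simulate_activation()].
#' @param sample_vertices 1-based vertex indices at which points are placed.
#' @param spec an [egm_spec()].
#' @param ref_annot reference-annotation time (ms) on the trace clock.
#' @param amplitudes optional per-point unipolar amplitudes (mV) overriding
#'   `spec$amplitude`, e.g. to imprint a voltage field on point voltages.
#' @param point_id optional clinical point ids (default 1..p).
#' @return An [eam_electric()].
#' @export
synthesize_electrograms <- function(mesh, lat, sample_vertices, spec = egm_spec(),
                                    ref_annot = 400, amplitudes = NULL,
                                    point_id = NULL) {
  p <- length(sample_vertices)
  t_star <- ref_annot + lat[sample_vertices]
  T_ <- spec$n_samples
  t_ms <- (seq_len(T_) - 1L) * 1000 / spec$fs
  if (any(t_star < min(t_ms)) || any(t_star > max(t_ms)))
    stop_eam("activation time outside the trace window", "eam_argument_error")
  A <- amplitudes %||% rep(spec$amplitude, p)
  uni1 <- uni2 <- matrix(0, p, T_)
  for (i in seq_len(p)) {
    uni1[i, ] <- egm_template(t_ms, t_star[i], A[i], spec$width)
    uni2[i, ] <- egm_template(t_ms, t_star[i] + spec$delay, A[i], spec$width)
  }
  bip0 <- uni1 - uni2
  set.seed(spec$seed)
  bip <- bip0 + matrix(rnorm(p * T_, 0, spec$noise_sd), p, T_)
  ref <- matrix(rep(egm_template(t_ms, ref_annot, 0.5, spec$width), each = p), p, T_)
  lat_rel <- t_star - ref_annot
  woi <- cbind(rep(min(0, min(lat_rel)) - 50, p), rep(max(lat_rel) + 50, p))
  pos <- mesh$vertices[sample_vertices, , drop = FALSE]
  ## raw catheter position: 0.5 mm outward along the vertex normal
  vn <- vertex_normals(mesh)[sample_vertices, , drop = FALSE]
  out_dir <- sign(rowSums(vn * pos)); out_dir[out_dir == 0] <- 1
  eam_electric(point_id = point_id %||% seq_len(p),
               egm_x = pos + vn * (0.5 * out_dir), egm_surf_x = pos,
               bip = bip, uni1 = uni1, uni2 = uni2, ref = ref,
               fs = spec$fs, trace_t0 = 0,
               ref_annot = rep(ref_annot, p), map_annot = t_star, woi = woi,
               voltage_bip = apply(bip0, 1, function(x) diff(range(x))),
               voltage_uni = apply(uni1, 1, function(x) diff(range(x))),
               impedance = rep(100, p))
}

#' Build a complete synthetic study fixture
#'
#' The package's default study conditions: a 30 mm chamber at subdivision
#' level 3 with five cut-outs (valve + four veins), a planar wave at
#' 1.0 m/s, 1 kHz electrograms, and points sampled at seeded random mesh
#' vertices. Ground truth for every downstream metric is attached as
#' attribute `"truth"`.
#'
#' @param n_points number of mapping points.
#' @param seed RNG seed controlling vertex sampling, jitter and noise.
#' @param wave a [wave_spec()].
#' @param chamber a [chamber_spec()].
#' @param egm an [egm_spec()].
#' @param patches voltage patch list for [simulate_voltage_field()].
#' @param background background voltage, mV.
#' @param n_location_only number of additional location-only points.
#' @param n_visitags number of synthetic ablation sites (0 for none).
#' @return An [eam_study()] with attribute `"truth"`.
#' @export
make_study_fixture <- function(n_points = 100, seed = 1L,
                               wave = wave_spec("planar", speed = 1),
                               chamber = chamber_spec(seed = seed),
                               egm = egm_spec(seed = seed),
                               patches = list(), background = 3,
                               n_location_only = 0, n_visitags = 0) {
  mesh <- make_chamber_mesh(chamber)
  act <- simulate_activation(mesh, wave)
  volt <- simulate_voltage_field(mesh, patches, background)
  set.seed(seed)
  samp <- sample(nrow(mesh$vertices), n_points,
                 replace = n_points > nrow(mesh$vertices))
  ## imprint the voltage field on point voltages exactly: peak-to-peak of
  ## the noiseless bipolar trace scales linearly with amplitude, so a unit
  ## first pass gives each point's own sampled p2p for rescaling
  ref_annot <- round(0.3 * egm$n_samples / egm$fs * 1000)
  el_unit <- synthesize_electrograms(mesh, act$lat, samp,
                                     egm_spec(fs = egm$fs, n_samples = egm$n_samples,
                                              amplitude = 1, width = egm$width,
                                              delay = egm$delay, noise_sd = 0,
                                              seed = egm$seed),
                                     ref_annot = ref_annot)
  amps <- volt$bip[samp] / el_unit$voltage_bip
  el <- synthesize_electrograms(mesh, act$lat, samp, egm, ref_annot = ref_annot,
                                amplitudes = amps)
  if (n_location_only > 0) {
    set.seed(seed + 7L)
    extra <- sample(nrow(mesh$vertices), n_location_only)
    pos <- mesh$vertices[extra, , drop = FALSE]
    T_ <- ncol(el$traces$bip)
    el2 <- eam_electric(
      point_id = c(el$point_id, max(as.numeric(el$point_id)) + seq_len(n_location_only)),
      egm_x = rbind(el$egm_x, pos), egm_surf_x = rbind(el$egm_surf_x, pos),
      tags = c(el$tags, rep(list("Location only"), n_location_only)),
      bip = rbind(el$traces$bip, matrix(NaN, n_location_only, T_)),
      uni1 = rbind(el$traces$uni1, matrix(NaN, n_location_only, T_)),
      uni2 = rbind(el$traces$uni2, matrix(NaN, n_location_only, T_)),
      ref = rbind(el$traces$ref, matrix(NaN, n_location_only, T_)),
      fs = el$fs, trace_t0 = el$trace_t0,
      ref_annot = c(el$ref_annot, rep(NaN, n_location_only)),
      map_annot = c(el$map_annot, rep(NaN, n_location_only)),
      woi = rbind(el$woi, matrix(c(-50, 50), n_location_only, 2, byrow = TRUE)),
      voltage_bip = c(el$voltage_bip, rep(NaN, n_location_only)),
      voltage_uni = c(el$voltage_uni, rep(NaN, n_location_only)),
      impedance = c(el$impedance, rep(NaN, n_location_only)))
    el <- el2
  }
  rf <- NULL
  if (n_visitags > 0) {
    set.seed(seed + 13L)
    vsamp <- sample(nrow(mesh$vertices), n_visitags)
    pos <- mesh$vertices[vsamp, , drop = FALSE]
    rf <- eam_visitags(tibble::tibble(
      x = pos[, 1] * 1.01, y = pos[, 2] * 1.01, z = pos[, 3] * 1.01,
      surf_x = pos[, 1], surf_y = pos[, 2], surf_z = pos[, 3],
      index_name = "ablation_index",
      index_value = runif(n_visitags, 300, 550),
      force = runif(n_visitags, 5, 40), power = runif(n_visitags, 25, 50),
      temperature = runif(n_visitags, 30, 43),
      impedance = runif(n_visitags, 80, 160),
      duration = runif(n_visitags, 10, 60)))
  }
  mesh$fields$act <- act$lat
  mesh$fields$bip <- volt$bip
  study <- eam_study(surface = mesh, electric = el, rfindex = rf,
                     system_name = "eamtools-synth",
                     notes = sprintf("synthetic fixture seed=%d n=%d", seed, n_points))
  ## point LATs recorded exactly as annotated (absolute-clock annotation
  ## minus reference), so annotation-derived metrics can be checked
  ## bit-exactly against the truth record
  attr(study, "truth") <- list(
    activation = act$truth, voltage = volt$truth,
    sample_vertices = samp,
    point_lat = el$map_annot[seq_len(n_points)] - el$ref_annot[seq_len(n_points)],
    n_points = n_points, n_location_only = n_location_only)
  study
}
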