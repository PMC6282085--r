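# Independent brute-force oracles used to verify the geometry, grid and
# threshold-selection code. These deliberately use different algorithms
# from the implementation (gift wrapping vs chull, angle summation vs ray
# casting, exhaustive loops vs vectorised sweeps).

# Convex hull area by gift wrapping (Jarvis march) + shoelace, on projected
# planar points. Independent of grDevices::chull.
oracle_hull_area <- function(x, y) {
  pts <- unique(data.frame(x = x, y = y))
  n <- nrow(pts)
  if (n < 3) return(0)
  start <- which.min(pts$x + 1e-9 * pts$y)
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- setdiff(seq_len(n), cur)
    nxt <- cand[1]
    for (k in cand[-1]) {
      cross <- (pts$x[nxt] - pts$x[cur]) * (pts$y[k] - pts$y[cur]) -
        (pts$y[nxt] - pts$y[cur]) * (pts$x[k] - pts$x[cur])
      if (cross < 0 ||
          (abs(cross) < 1e-12 &&
           (pts$x[k] - pts$x[cur])^2 + (pts$y[k] - pts$y[cur])^2 >
           (pts$x[nxt] - pts$x[cur])^2 + (pts$y[nxt] - pts$y[cur])^2)) {
        nxt <- k
      }
    }
    cur <- nxt
    if (cur == start) break
    if (length(hull) > n) stop("gift wrapping failed to close")
  }
  hx <- pts$x[hull]; hy <- pts$y[hull]
  m <- length(hx)
  j <- c(m, seq_len(m - 1))
  abs(sum(hx[j] * hy - hx * hy[j])) / 2
}

# EOO oracle: same projection contract, independent hull + area.
oracle_eoo <- function(lon, lat) {
  keep <- !is.na(lon) & !is.na(lat)
  lon <- lon[keep]; lat <- lat[keep]
  if (length(lon) < 3) return(0)
  xy <- herbassess:::equal_area_project(lon, lat)
  xy <- unique(round(xy, 6))
  if (nrow(xy) < 3) return(0)
  a <- oracle_hull_area(xy$x, xy$y)
  if (a < 1e-9) 0 else a
}

# Occupied-cell count by brute-force pairwise comparison of cell indices.
oracle_cell_count <- function(lon, lat, cell_km, origin = c(0, 0)) {
  keep <- !is.na(lon) & !is.na(lat)
  xy <- herbassess:::equal_area_project(lon[keep], lat[keep])
  if (nrow(xy) == 0) return(0L)
  ij <- cbind(floor((xy$x - origin[1] + cell_km / 2) / cell_km),
              floor((xy$y - origin[2] + cell_km / 2) / cell_km))
  count <- 0L
  for (i in seq_len(nrow(ij))) {
    seen <- FALSE
    for (k in seq_len(i - 1)) {
      if (ij[i, 1] == ij[k, 1] && ij[i, 2] == ij[k, 2]) { seen <- TRUE; break }
    }
    if (!seen) count <- count + 1L
  }
  count
}

# Point-in-polygon by winding (angle summation) — independent of the ray
# casting used in the package. Boundary points are treated as inside.
oracle_point_in_ring <- function(px, py, ring) {
  n <- nrow(ring) - 1
  total <- 0
  for (i in seq_len(n)) {
    ax <- ring[i, 1] - px; ay <- ring[i, 2] - py
    bx <- ring[i + 1, 1] - px; by <- ring[i + 1, 2] - py
    if (sqrt(ax^2 + ay^2) < 1e-12 || sqrt(bx^2 + by^2) < 1e-12) return(TRUE)
    cross <- ax * by - ay * bx
    dot <- ax * bx + ay * by
    if (abs(cross) < 1e-12 && dot <= 0) return(TRUE)  # on segment
    total <- total + atan2(cross, dot)
  }
  abs(total) > pi  # ~2*pi inside, ~0 outside
}

# First containing unit in layer order, brute force over all units.
oracle_locality <- function(px, py, layer) {
  for (u in layer$units) {
    if (oracle_point_in_ring(px, py, u$ring)) return(u$unit_id)
  }
  NA_character_
}

# Exhaustive specimen-count threshold sweep.
oracle_count_threshold <- function(n_specimens, threatened, candidates) {
  best_t <- NA_integer_; best_acc <- -1
  for (t in candidates) {
    correct <- 0
    for (i in seq_along(n_specimens)) {
      pred <- n_specimens[i] < t
      if (pred == threatened[i]) correct <- correct + 1
    }
    acc <- correct / length(n_specimens)
    if (acc > best_acc) { best_acc <- acc; best_t <- t }
  }
  list(threshold = best_t, accuracy = best_acc)
}

# Small labelled prediction/reference fixture for the evaluation layer.
make_eval_fixture <- function(tp, fn, tn, fp, approach = "m", group = "G1") {
  n <- tp + fn + tn + fp
  ids <- sprintf("s%03d", seq_len(n))
  ref_cat <- c(rep("CR", tp), rep("EN", fn), rep("LC", tn), rep("NT", fp))
  pred_bin <- c(rep("threatened", tp), rep("not_threatened", fn),
                rep("not_threatened", tn), rep("threatened", fp))
  list(
    predictions = data.frame(species_id = ids, approach = approach,
                             category = NA_character_, binary = pred_bin,
                             stringsAsFactors = FALSE),
    references = data.frame(species_id = ids, reference_category = ref_cat,
                            group_label = group, stringsAsFactors = FALSE))
}

# Random metrics table for classifier property tests.
random_metrics <- function(n, seed) {
  set.seed(seed)
  data.frame(
    species_id = sprintf("r%03d", seq_len(n)),
    n_specimens = sample(1:60, n, replace = TRUE),
    n_georeferenced = sample(1:40, n, replace = TRUE),
    n_localities = sample(1:10, n, replace = TRUE),
    eoo_km2 = 10^runif(n, 0, 6),
    n_occupied_cells = sample(1:300, n, replace = TRUE),
    n_locations = sample(1:40, n, replace = TRUE),
    stringsAsFactors = FALSE) -> m
  m$aoo_km2 <- 4 * m$n_occupied_cells
  m
}
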