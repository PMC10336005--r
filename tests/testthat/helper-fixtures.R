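# Canonical study constants used across tests
paper_k <- function() dissociation_constants(k8 = 370e-6, k16 = 3.0e-13)

canonical_model <- function() self_assoc_model(c(1L, 2L, 4L))

truth_log10_kd <- function() log10(c(370e-6, 3.0e-13))

# Independent root-finding oracle for the species equilibrium: stats::uniroot
# on the monotone conservation equation (the implementation uses its own
# bisection).
oracle_free_tetramer <- function(total, k) {
  stats::uniroot(function(c4) c4 + 2 * c4^2 / k$k8 + 4 * c4^4 / k$k16 - total,
                 c(0, total), tol = 1e-18)$root
}

# Closed-form circumcircle of a triangle (oracle for 3-point circle fits)
oracle_circumcircle <- function(x, y) {
  ax <- x[1]; ay <- y[1]; bx <- x[2]; by <- y[2]; cx <- x[3]; cy <- y[3]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center_x = ux, center_y = uy, radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

# Small localization table with known trace lengths
make_traces <- function(lengths, sd = 0, centers = NULL, photons = 100) {
  rows <- lapply(seq_along(lengths), function(i) {
    n <- lengths[i]
    ctr <- if (is.null(centers)) c(0, 0, 0) else centers[i, ]
    data.frame(trace_id = i, t_s = seq_len(n) * 1e-3,
               x_nm = ctr[1] + stats::rnorm(n, 0, sd),
               y_nm = ctr[2] + stats::rnorm(n, 0, sd),
               z_nm = ctr[3] + stats::rnorm(n, 0, sd),
               photons = rep_len(photons, n))
  })
  do.call(rbind, rows)
}
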