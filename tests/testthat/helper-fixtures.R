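# Shared fixtures and independent oracles. Everything here is built in code
# at test time; nothing is read from disk.

# small world grid: 41^3 voxels of 1 mm covering -20..20 mm
test_grid <- function(voxel_size = 1, half_extent = 20) {
  n <- as.integer(2 * half_extent / voxel_size) + 1L
  mask_grid(c(n, n, n), voxel_size = voxel_size,
            origin = rep(-half_extent, 3))
}

# a straight streamline between two points with n vertices
straight_fiber <- function(from, to, n = 2) {
  cbind(seq(from[1], to[1], length.out = n),
        seq(from[2], to[2], length.out = n),
        seq(from[3], to[3], length.out = n))
}

random_tractogram <- function(n = 10, seed = 1, sd = 15, n_pts = 6) {
  set.seed(seed)
  tractogram(lapply(seq_len(n), function(i) matrix(rnorm(n_pts * 3, sd = sd), n_pts, 3)),
             space = "synthetic")
}

# cohort of spherical stimulations on a template grid
sphere_cohort <- function(centers, radii, template, improvements = NULL,
                          amplitudes = NULL, name = "test", space = "synthetic") {
  n <- nrow(centers)
  improvements <- improvements %||% seq(10, by = 5, length.out = n)
  amplitudes <- amplitudes %||% rep(1, n)
  records <- lapply(seq_len(n), function(i) {
    stimulation_record(stim_id = sprintf("%s_s%02d", name, i),
                       patient_id = sprintf("%s_p%02d", name, i),
                       cohort = name,
                       masks = list(sphere_mask(centers[i, ], radii[i], template)),
                       amplitude = amplitudes[i],
                       improvement_pct = improvements[i])
  })
  cohort_table(records, name = name, space = space)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent connectivity oracle -------------------------------------
# Re-implements the declared connectivity semantics without touching the
# package's mask/affine/incidence code: every segment is subdivided into
# ceiling(len/step) equal parts (vertices kept), each sampled point is mapped
# through the inverse affine by hand, rounded to its nearest voxel, and the
# voxel CENTER is tested analytically against each sphere (no mask array is
# ever built). Returns a dense 0/1 fiber x sphere matrix.
oracle_sphere_incidence <- function(streamlines, sphere_centers, sphere_radii,
                                    affine, grid_dim, step = 0.05) {
  ainv <- solve(affine)
  nf <- length(streamlines)
  ns <- nrow(sphere_centers)
  out <- matrix(0L, nf, ns)
  for (f in seq_len(nf)) {
    pts <- streamlines[[f]]
    samp <- pts[1, , drop = FALSE]
    for (i in seq_len(nrow(pts) - 1)) {
      seg <- pts[i + 1, ] - pts[i, ]
      len <- sqrt(sum(seg^2))
      k <- max(1L, as.integer(ceiling(len / step - 1e-12)))
      fr <- seq_len(k) / k
      samp <- rbind(samp, sweep(outer(fr, seg), 2, pts[i, ], "+"))
    }
    # by-hand inverse affine, nearest voxel, in-grid filter
    hom <- cbind(samp, 1) %*% t(ainv)
    v <- floor(hom[, 1:3, drop = FALSE] + 0.5)
    ok <- v[, 1] >= 0 & v[, 1] < grid_dim[1] &
      v[, 2] >= 0 & v[, 2] < grid_dim[2] &
      v[, 3] >= 0 & v[, 3] < grid_dim[3]
    if (!any(ok)) next
    centers <- cbind(v[ok, , drop = FALSE], 1) %*% t(affine)
    for (s in seq_len(ns)) {
      d2 <- rowSums(sweep(centers[, 1:3, drop = FALSE], 2, sphere_centers[s, ])^2)
      if (any(d2 <= sphere_radii[s]^2)) out[f, s] <- 1L
    }
  }
  out
}

# rank-sum (Mann-Whitney) AUC of scores for positives vs negatives
rank_auc <- function(scores, is_positive) {
  r <- rank(scores)
  n1 <- sum(is_positive)
  n0 <- sum(!is_positive)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# random incidence structure for statistic tests: each fiber connected to a
# random subset of stimulations (sizes spanning valid and invalid cases)
random_incidence <- function(n_fibers, n_stims, seed = 1) {
  set.seed(seed)
  entries <- matrix(FALSE, n_fibers, n_stims)
  for (f in seq_len(n_fibers)) {
    k <- sample(0:n_stims, 1)
    if (k > 0) entries[f, sample(n_stims, k)] <- TRUE
  }
  incidence_matrix(entries, seq_len(n_fibers), sprintf("s%03d", seq_len(n_stims)))
}
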