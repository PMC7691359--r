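# shared fixtures: all data is generated in code, nothing is stored on disk

# tiny wave-optics config for fast propagation tests
tiny_optical <- function(...) {
  desk_optical_config(sensor_shape = c(24L, 32L),
                      channel_to_sensor_distance = 0.5e-3, ...)
}

# fast parametric config for pipeline-level tests
parametric_optical <- function(...) {
  desk_optical_config(propagation = "parametric", ...)
}

# difference_samples filled with iid gaussian noise (a null "class")
noise_samples <- function(n, shape = c(8, 8), sid = "s", label = NA_character_) {
  img <- matrix(stats::rnorm(n * prod(shape)), n, prod(shape))
  holocyto:::new_difference_samples(
    img, shape,
    data.frame(frame_index = seq_len(n) * 2L, P = rowSums(img^2),
               session_id = rep(sid, length.out = n),
               label = rep(label, length.out = n), stringsAsFactors = FALSE))
}

null_session_dataset <- function(N_s = 4, n_per_session = 30, shape = c(8, 8),
                                 seed = 5) {
  holocyto:::with_seed(seed, {
    pairs <- lapply(seq_len(N_s), function(i) {
      list(A = noise_samples(n_per_session, shape, paste0("a", i)),
           B = noise_samples(n_per_session, shape, paste0("b", i)))
    })
    session_dataset(pairs)
  })
}

# O(nA * nB) pairwise win-counting oracle for the Mann-Whitney statistic:
# U_A = #{a > b} + 0.5 #{a == b}; the separation uses the symmetrised U
oracle_separation <- function(a, b) {
  u_a <- 0
  for (x in a) for (y in b) u_a <- u_a + (x > y) + 0.5 * (x == y)
  nm <- length(a) * length(b)
  center <- (nm + 1) / 2
  abs(max(u_a, nm - u_a) - center) / center
}

# independent re-implementation of the acceptance rule for recount oracles
oracle_accept_count <- function(P, theta) {
  acc <- 0L; prev <- FALSE
  for (p in P) {
    cur <- (p > theta) && !prev
    acc <- acc + cur
    prev <- cur
  }
  acc
}

# the acceptance-scale synthetic campaign is expensive; build it once and
# share it between the acceptance criteria that use it
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_experiment <- function() {
  if (is.null(.acceptance_cache$res)) {
    .acceptance_cache$res <- run_experiment(list(
      seed = 7, N_s = 11, n_frames_per_session = 800, factor = 2,
      target_R = 0.04))
  }
  .acceptance_cache$res
}

# contrastless (equal-diameter) beads for the bias-reproduction criterion
contrastless_bead <- function(label) {
  bead_class(label, mean_diameter = 17e-6, diameter_sd = 0.55e-6,
             concentration_per_ml = 2.2e4)
}

contrastless_biased_dataset <- function(N_s = 4, n_frames = 500, seed = 21) {
  plan <- make_intertwined_dataset(
    N_s, contrastless_bead("A"), contrastless_bead("B"),
    desk_optical_config(), flow_config(),
    acquisition_config(session_duration = n_frames / 138),
    session_drift_model(drift_class_correlation = 1), seed = seed)
  preprocess_plan(plan, target_R = 0.04, factor = 2)$dataset
}
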