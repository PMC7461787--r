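# shared fixtures, built in code

# truth velocity at absolute session times, zero during the static period
truth_velocity_at <- function(truth, t_session) {
  s <- t_session - truth$static_duration
  ifelse(s >= 0, truth$v_fun(pmax(s, 0)), 0)
}

# noiseless sessions are reused across several files; memoise per distance
.noiseless_cache <- new.env(parent = emptyenv())
noiseless_session <- function(distance) {
  key <- as.character(distance)
  if (is.null(.noiseless_cache[[key]]))
    .noiseless_cache[[key]] <- sprint_session(distance = distance,
                                              noise = noise_free())
  .noiseless_cache[[key]]
}

.fit_cache <- new.env(parent = emptyenv())
noiseless_fit <- function(distance) {
  key <- as.character(distance)
  if (is.null(.fit_cache[[key]])) {
    ses <- noiseless_session(distance)
    .fit_cache[[key]] <- sprint_velocity(ses$imu, ses$gnss, ses$config)
  }
  .fit_cache[[key]]
}
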