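# Shared fixtures, built once per test run (lazily) and reused; everything
# is generated in code with fixed seeds.

.fx <- new.env(parent = emptyenv())

fixture_subject <- function() {
  if (is.null(.fx$sub)) .fx$sub <- make_subject(seed = 42L, cohort = "PiB+",
                                                noise = 0)
  .fx$sub
}

fixture_idaif_fit <- function() {
  if (is.null(.fx$fit)) {
    sub <- fixture_subject()
    .fx$fit <- fit_idaif(sub$tacs$cerebellum, sub$croia, sub$cbg,
                         r = sub$r, pf = sub$pf, seed = 7L)
  }
  .fx$fit
}

fixture_phantom <- function() {
  if (is.null(.fx$ph)) .fx$ph <- make_vessel_phantom(seed = 5L)
  .fx$ph
}

# uniform fine schedule for continuous-limit checks
dense_schedule <- function(dur = 0.05, t_end = 60) {
  n <- round(t_end / dur)
  frame_schedule(start = (seq_len(n) - 1) * dur, duration = rep(dur, n))
}
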