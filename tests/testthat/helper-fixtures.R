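## Shared fixtures, built once per session and cached: simulations are the
## expensive part of this suite, so files reuse a small set of canonical
## records instead of regenerating them.

kB_test <- 1.380649e-23

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

## 135-s constant-drag record (no binding): ~105 one-second segments after
## the 30-s discard. Used by spectral unit tests.
control_sim_135 <- function() cached_fixture("sim135", {
  traj <- simulate_trajectory(trap_config(),
                              binding_schedule(ligand_conc = 0),
                              sim_config(duration = 135, seed = 42))
  list(traj = traj, rec = render_qpd(traj, particle_id = "ctrl42"))
})

control_gamma_135 <- function() cached_fixture("gamma135", {
  gamma_trajectory(control_sim_135()$rec, axes = "x")
})

## default-world drag of the bare bead
gamma_bare <- function() stokes_drag(2.4e-6, 8.9e-4)

## theoretical corner frequency of the default trap
fc_theory <- function() 1e-5 / (2 * pi * gamma_bare())

## a short binding record with a fast transition, for plumbing tests
binding_sim_fast <- function() cached_fixture("bindfast", {
  sched <- binding_schedule(ligand_conc = 5e-8)  # Kobs = 0.05 /s
  traj <- simulate_trajectory(trap_config(), sched,
                              sim_config(duration = 90, seed = 11))
  list(traj = traj, rec = render_qpd(traj, particle_id = "bind11"),
       schedule = sched)
})
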