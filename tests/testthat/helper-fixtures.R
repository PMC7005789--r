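# Shared fixtures: all inputs are generated in code at test time.

# minimal free-energy-estimate stand-in for aggregation tests
fake_estimate <- function(dG_kcal, converged = TRUE) {
  structure(list(delta_G_kcal = dG_kcal, converged = converged,
                 estimator = "MBAR"), class = "fep_estimate")
}

# write a K-state set of dhdl-style xvg files with cross-evaluation columns
# u is an n x K reduced-potential matrix per state (kT); energies are written
# in kJ/mol at the given temperature
write_dhdl_fixture <- function(dir, u_per_state, lambdas, temperature = 300,
                               dt_ps = 10) {
  kT <- fepddg::kT_kJ_per_mol(temperature)
  paths <- character(length(u_per_state))
  for (k in seq_along(u_per_state)) {
    u <- u_per_state[[k]]
    n <- nrow(u)
    labels <- c("dH/d\\xl\\f{} \\xl\\f{}",
                paste0("\\xD\\f{}H \\xl\\f{} to ", sprintf("%.4f", lambdas)))
    s <- structure(list(times = (seq_len(n) - 1) * dt_ps,
                        column_labels = labels,
                        values = cbind(rep(0, n), u * kT),
                        temperature = temperature),
                   class = "fep_xvg")
    paths[k] <- file.path(dir, sprintf("dhdl_state%d.xvg", k))
    fepddg::write_xvg(s, paths[k])
  }
  paths
}

# forward/reverse work samples extracted from a 2-state reduced potential set
work_pair <- function(rps) {
  list(fwd = rps$u[rps$origin == 1L, 2L] - rps$u[rps$origin == 1L, 1L],
       rev = rps$u[rps$origin == 2L, 1L] - rps$u[rps$origin == 2L, 2L])
}
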