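# Shared test helpers.

# The bundled SOC MoH total intentionally differs from its category sum by
# $9 (the published figure is kept); silence that known reconciliation
# warning where it is not the subject of the test.
quiet_model <- function() suppressWarnings(prp_decision_model())

# Mean and SD of a normal truncated below at `min` (oracle for the
# cohort generator's continuous covariates).
truncnorm_moments <- function(mean, sd, min) {
  a <- (min - mean) / sd
  lambda <- dnorm(a) / (1 - pnorm(a))
  mu <- mean + sd * lambda
  v <- sd^2 * (1 + a * lambda - lambda^2)
  c(mean = mu, sd = sqrt(v))
}

# Patient records with exact arm-level FIR counts (covariates absent).
records_from_counts <- function(fir_prp, n_prp, fir_soc, n_soc) {
  tibble::tibble(
    arm = c(rep("PRP", n_prp), rep("SOC", n_soc)),
    fir = c(rep(1L, fir_prp), rep(0L, n_prp - fir_prp),
            rep(1L, fir_soc), rep(0L, n_soc - fir_soc))
  )
}

# Minimal draw table for ceac()/plane_summary() property tests.
draws_tbl <- function(delta_cost, delta_effect) {
  tibble::tibble(
    delta_cost = delta_cost,
    delta_effect = delta_effect,
    quadrant = refillcea:::plane_quadrant(delta_cost, delta_effect)
  )
}

write_config <- function(cfg) {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  yaml::write_yaml(cfg, path)
  path
}

# The bundled parameter set as an editable R list.
base_config_list <- function() {
  yaml::read_yaml(system.file("extdata", "idi_prp_params.yaml",
                              package = "refillcea"))
}
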