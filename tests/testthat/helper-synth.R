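# shared fixtures and independent oracles used across test files

noise_free_params <- function(...) {
  truth_params(sigma_A = 0, sigma_phi = 0, sigma_gsw = 0, ...)
}

# independently coded resistor-chain evaluation of the anatomical model:
# plain serial arithmetic, no shared code with compose_gm()
oracle_anat_gm <- function(a, const = diffusion_constants()) {
  g_cw <- const$Dw * const$rf_cw * const$p_cw / (a$Tcw * 1e-6)
  g_cyt <- const$Dw * const$rf_cyt * const$p_cyt / (a$Tcyt * 1e-6)
  g_st <- const$Dw * const$rf_st * const$p_st / (a$Tchl / 2 * 1e-6)
  r_liq <- 1 / (g_cw * a$Sm) + 1 / (const$g_pl * a$Sm) +
    1 / (g_cyt * a$Sc) + 1 / (const$g_env * a$Sc) +
    1 / (g_st * a$Sc)
  g_ias <- const$Da * a$f_ias / ((a$Tleaf * 1e-6 / 2) * const$tau)
  gm_ms <- 1 / (1 / g_ias + (8.314 * const$Tk / const$H) * r_liq)
  list(r_liq = r_liq, g_ias = g_ias, gm_ms = gm_ms,
       gm_mol = gm_ms * const$pressure / (8.314 * const$Tk))
}

# random valid anatomy draws for property tests
random_anatomy <- function(n) {
  sm <- runif(n, 8, 30)
  tibble::tibble(
    Tleaf = runif(n, 40, 200),
    f_ias = runif(n, 0.05, 0.6),
    Sm = sm,
    Sc = sm * runif(n, 0.5, 1),
    Tcw = runif(n, 0.05, 0.4),
    Tcyt = runif(n, 0.01, 0.5),
    Tchl = runif(n, 0.5, 4)
  )
}

# writes a small canonical gas-exchange CSV and returns its path
write_gasex_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
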