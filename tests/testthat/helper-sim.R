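# Shared fixtures for the test suite: small simulated datasets and
# independent oracles, all built in code.

# Small breeding dataset: quick historical phase, few generations.
small_sim <- function(h2 = 0.4, n_generations = 2, n_sires = 5, n_dams = 20,
                      progeny_per_dam = 6, selection = "random",
                      n_loci = 1200, n_markers = 600, n_qtl = 90,
                      ne = 60, hist_gen = 60) {
  g <- genome_spec(9, 1.5, n_loci)
  pool <- simulate_historical(g, ne = ne, n_gen = hist_gen)
  map <- assign_loci(pool, 0.1, n_qtl = n_qtl, n_markers = n_markers)
  cfg <- sim_config(n_sires = n_sires, n_dams = n_dams,
                    progeny_per_dam = progeny_per_dam,
                    n_generations = n_generations, h2 = h2,
                    selection = selection)
  simulate_breeding(cfg, pool, map)
}

# Independent naive leave-one-out oracle: refit the mixed model with
# individual i's phenotype dropped, using the GLS/BLUP closed form on the
# pre-adjusted phenotypes (mean estimated once on the full data, matching
# the loo_ebv() contract).
naive_loo <- function(K, phen, h2) {
  n <- nrow(phen)
  lambda <- (1 - h2) / h2
  o <- match(as.character(phen$id), rownames(K))
  Koo <- K[o, o, drop = FALSE]
  Vinv <- solve(Koo + diag(lambda, n))
  one <- rep(1, n)
  mu <- sum(Vinv %*% phen$value) / sum(Vinv %*% one)
  ys <- phen$value - mu
  vapply(seq_len(n), function(i) {
    Vi <- Koo[-i, -i, drop = FALSE] + diag(lambda, n - 1)
    as.numeric(Koo[i, -i, drop = FALSE] %*% solve(Vi, ys[-i]))
  }, numeric(1))
}

# Closed-form GBLUP oracle for a fully phenotyped set:
# g_hat = G (G + lambda I)^-1 (y - mu_hat), mu_hat by GLS.
gblup_closed_form <- function(G, y, h2) {
  lambda <- (1 - h2) / h2
  Vinv <- solve(G + diag(lambda, nrow(G)))
  mu <- sum(Vinv %*% y) / sum(Vinv %*% rep(1, length(y)))
  as.numeric(G %*% Vinv %*% (y - mu))
}

# Parameter grid used by the algebraic roundtrip properties.
roundtrip_grid <- expand.grid(q2 = c(0.5, 0.8, 1), h2 = c(0.1, 0.4, 0.9))
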