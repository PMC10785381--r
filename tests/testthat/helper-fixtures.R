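# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Moderate above-ground experiment (40 lines, 1 bed x 2 units x 60 rows,
# 240 records) with a converged AM fit and its LOO cross-validation.
shared_am <- function() {
  cached("am", {
    cfg <- sim_config(seed = 101, n_lines = 40, n_snps = 800,
                      beds = 1, units_per_bed = 2, rows_per_unit = 60)
    sim <- simulate_above_ground(cfg)
    spec <- build_am(sim$records, "y", sim$grm, sim$spatial)
    fit <- suppressWarnings(reml_fit(spec, max_iter = 150))
    cv <- loo_cv(fit)
    list(cfg = cfg, sim = sim, spec = spec, fit = fit, cv = cv)
  })
}

# Reference genetic-parameter tables shipped with the package.
reference_table <- function(which) {
  path <- system.file("extdata",
                      paste0("reference_", which, ".tsv"), package = "nnagp")
  read.delim(path, check.names = FALSE)
}

# Named variance-component vector for one row of a reference VC table.
reference_vc <- function(tab, trait, model) {
  row <- tab[tab$trait == trait & tab$model == model, ]
  comps <- intersect(c("g", "l", "ng", "nl", "r", "tg", "tl",
                       "s1", "s2", "s3", "e"), names(tab))
  stats::setNames(as.numeric(row[comps]), comps)
}
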