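# Shared fixtures, built once per test session and memoised.  The heavier
# benchmarks (1 Mb detector genome, census genome) are also reused by the
# acceptance tests.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

fx_library <- function() fx_memo("lib", load_domain_library)

fx_gypsy_template <- function() fx_memo("tmpl_g", function()
  family_template("benchG", "Gypsy", ltr_len = 350L, seed = 101L))

fx_copia_template <- function() fx_memo("tmpl_c", function()
  family_template("benchC", "Copia", ltr_len = 350L, seed = 202L))

# clean detector benchmark: 20 full-length elements (2 families), ages up
# to 10 MY, 1 Mb genome, no truncation
fx_detect_benchmark <- function() fx_memo("bench_detect", function() {
  bg <- simulate_background(1e6, 0.5, seed = 301L, seq_id = "chrB")
  insert_elements(bg, list(fx_gypsy_template(), fx_copia_template()),
                  simulation_config(n_insertions = 10L,
                                    ages = c(1e6, 2.5e6, 5e6, 7.5e6, 10e6),
                                    seed = 302L))
})

fx_detect_candidates <- function() fx_memo("bench_detect_cand", function()
  detect_ltr_elements(fx_detect_benchmark()$genome))

# census benchmark: 2 families x (10 full + 5 truncated + 5 solo), 1 Mb
fx_census_benchmark <- function() fx_memo("bench_census", function() {
  bg <- simulate_background(1e6, 0.5, seed = 401L, seq_id = "chrC")
  insert_elements(bg, list(fx_gypsy_template(), fx_copia_template()),
                  simulation_config(n_insertions = 20L,
                                    ages = c(1e6, 5e6),
                                    truncation_fraction = 1 / 3,
                                    solo_ltr_fraction = 0.25,
                                    seed = 402L))
})

# small aged simulation reused by classification/dating/census unit tests
fx_small_sim <- function() fx_memo("small_sim", function() {
  bg <- simulate_background(3e5, 0.5, seed = 501L)
  insert_elements(bg, list(fx_gypsy_template(), fx_copia_template()),
                  simulation_config(n_insertions = 4L, ages = c(2.5e6, 5e6),
                                    seed = 502L))
})

fx_small_detected <- function() fx_memo("small_det", function()
  detect_ltr_elements(fx_small_sim()$genome))

# diverged RT peptides for phylogeny tests: two ancestral RT nucleotide
# sequences, each giving rise to a small clade, plus a distant outgroup
fx_rt_peptides <- function() fx_memo("rt_peps", function() {
  lib <- fx_library()
  rt <- lib$peptides[[grep("^RT:gypsy", names(lib$peptides))[1]]]
  with_seed <- function(seed, expr) {   # local copy; package helper not exported
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); force(expr)
  }
  mut_pep <- function(p, n_sub, aas = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
    ch <- strsplit(p, "")[[1]]
    idx <- sample(seq_along(ch), n_sub)
    ch[idx] <- sample(aas, n_sub, replace = TRUE)
    paste(ch, collapse = "")
  }
  with_seed(601L, {
    ancA <- mut_pep(rt, 30L)  # two diverged ancestors from one core
    ancB <- mut_pep(rt, 30L)
    out <- mut_pep(rt, 80L)   # distant outgroup
    peps <- c(A1 = mut_pep(ancA, 4L), A2 = mut_pep(ancA, 4L), A3 = mut_pep(ancA, 4L),
              B1 = mut_pep(ancB, 4L), B2 = mut_pep(ancB, 4L), B3 = mut_pep(ancB, 4L),
              OUT = out)
    peps
  })
})
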