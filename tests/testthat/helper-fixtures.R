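# Fixtures generated in code: small atlases, quick cohorts, and a
# factor-model correlation matrix used as a subject similarity kernel.

small_atlas <- function(g = 4, s = 4, a = 1) {
  suppressWarnings(make_default_atlas(g, s, a))
}

quick_cohort <- function(n_subjects = 3, n_sessions = 1,
                         atlas = small_atlas(), seed = 1, ...) {
  simulate_cohort(
    simulation_config(n_subjects = n_subjects, n_sessions = n_sessions,
                      seed = seed, ...),
    atlas)
}

session1_networks <- function(cohort, ...) {
  lapply(build_cohort_networks(cohort, ...), `[[`, 1)
}

# correlation matrix with k latent factors: realistic off-diagonal spread,
# guaranteed positive definite
random_corr <- function(n, k = 5, seed = 1) {
  withr::with_seed(seed, {
    L <- matrix(stats::rnorm(n * k), n, k)
    S <- tcrossprod(L) + diag(n)
    D <- sqrt(diag(S))
    S / tcrossprod(D)
  })
}

write_atlas_tsv <- function(atlas, path = tempfile(fileext = ".tsv")) {
  utils::write.table(atlas, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}
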