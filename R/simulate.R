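#' Default synthetic parcellation table
#'
#' Builds a bilateral region table with the class composition of the
#' Destrieux surface parcellation: per hemisphere, 29 gyral, 31 sulcal and
#' 14 ambiguous regions (74 per hemisphere, 148 total). Region names are
#' synthetic placeholders; the table reproduces only the class counts, not
#' the anatomical label assignment, which is user input in real analyses.
#'
#' @param n_gyral_per_hemi,n_sulcal_per_hemi,n_ambiguous_per_hemi
#'   per-hemisphere region counts.
#' @return Region table data frame (see [load_region_table()]).
#' @export
#' @examples
#' atlas <- make_default_atlas()
#' table(atlas$region_class)
make_default_atlas <- function(n_gyral_per_hemi = 29,
                               n_sulcal_per_hemi = 31,
                               n_ambiguous_per_hemi = 14) {
  stopifnot(n_gyral_per_hemi >= 0, n_sulcal_per_hemi >= 0,
            n_ambiguous_per_hemi >= 0)
  one_hemi <- function(hemi, offset) {
    cls <- rep(c("gyral", "sulcal", "ambiguous"),
               c(n_gyral_per_hemi, n_sulcal_per_hemi, n_ambiguous_per_hemi))
    within_class_idx <- stats::ave(seq_along(cls), cls, FUN = seq_along)
    data.frame(
      region_id = offset + seq_along(cls) - 1L,
      name = sprintf("%s_%s_%02d", hemi,
                     c(gyral = "G", sulcal = "S", ambiguous = "A")[cls],
                     within_class_idx),
      hemisphere = hemi,
      region_class = cls,
      stringsAsFactors = FALSE
    )
  }
  n_per_hemi <- n_gyral_per_hemi + n_sulcal_per_hemi + n_ambiguous_per_hemi
  atlas <- rbind(one_hemi("L", 0L), one_hemi("R", n_per_hemi))
  validate_region_table(atlas)
}

#' Simulation configuration for synthetic cohorts
#'
#' Collects the generative parameters of the synthetic cohort model with
#' defaults emulating cortical-thickness-like feature maps (values in mm).
#' Vertex values for region r, subject s, session t are drawn as
#' Normal(mu_r + delta_sr + eps_srt, sigma_r) where mu_r is a class-level
#' mean plus Normal(0, tau_class) dispersion, sigma_r is a region-level
#' within-region SD (lognormal around `sigma_within` with log-SD
#' `sigma_within_cv` — real regions differ in feature heterogeneity, and
#' broad-distribution regions overlap many others, which gives the
#' similarity networks the hub structure underlying their small-world
#' topology), delta_sr ~ Normal(0, sigma_subject^2) is a stable
#' subject-by-region effect and eps_srt ~ Normal(0, sigma_session^2) is
#' session noise. In the patient group, sulcal region means receive an
#' extra cohort-level perturbation Normal(0, group_effect^2), increasing
#' sulcal mean dispersion and hence lowering S-S similarity.
#'
#' @param n_subjects number of subjects (>= 2 for any estimation stage).
#' @param n_sessions repeated sessions per subject (>= 1).
#' @param n_patients how many subjects carry the group effect (labelled
#'   `"patient"`, the rest `"control"`).
#' @param vertices_per_region vertex samples per region.
#' @param mu_gyral,mu_sulcal class-level mean feature values.
#' @param tau_gyral,tau_sulcal class-level SD of region means.
#' @param sigma_within median within-region vertex SD (> 0).
#' @param sigma_within_cv log-SD of the lognormal region-level dispersion
#'   of within-region SDs (0 gives every region the same SD).
#' @param sigma_subject SD of the stable subject-by-region effect.
#' @param sigma_session SD of the session-specific noise.
#' @param group_effect SD of the sulcal mean perturbation in patients.
#' @param group_age_shift mean age offset for patients (0 keeps covariates
#'   independent of group, avoiding confounded tests).
#' @param seed RNG seed; identical config + seed gives identical cohorts.
#' @return A `morph_sim_config` list.
#' @export
simulation_config <- function(n_subjects = 20,
                              n_sessions = 1,
                              n_patients = 0,
                              vertices_per_region = 200,
                              mu_gyral = 2.7,
                              mu_sulcal = 2.3,
                              tau_gyral = 0.15,
                              tau_sulcal = 0.15,
                              sigma_within = 0.5,
                              sigma_within_cv = 0.25,
                              sigma_subject = 0.1,
                              sigma_session = 0.05,
                              group_effect = 0,
                              group_age_shift = 0,
                              seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_sessions = as.integer(n_sessions),
              n_patients = as.integer(n_patients),
              vertices_per_region = as.integer(vertices_per_region),
              mu_gyral = mu_gyral, mu_sulcal = mu_sulcal,
              tau_gyral = tau_gyral, tau_sulcal = tau_sulcal,
              sigma_within = sigma_within,
              sigma_within_cv = sigma_within_cv,
              sigma_subject = sigma_subject,
              sigma_session = sigma_session,
              group_effect = group_effect,
              group_age_shift = group_age_shift,
              seed = as.integer(seed))
  if (cfg$n_sessions < 1) stop("n_sessions must be >= 1")
  if (cfg$vertices_per_region < 1) stop("vertices_per_region must be positive")
  if (cfg$sigma_within <= 0) stop("sigma_within must be > 0")
  for (f in c("tau_gyral", "tau_sulcal", "sigma_within_cv", "sigma_subject",
              "sigma_session", "group_effect")) {
    if (cfg[[f]] < 0) stop(f, " must be >= 0")
  }
  if (cfg$n_patients > cfg$n_subjects) stop("n_patients exceeds n_subjects")
  class(cfg) <- "morph_sim_config"
  cfg
}

#' Simulate a cohort of vertex-wise feature maps
#'
#' Draws region means once per cohort (inter-regional similarity structure
#' is a cohort-level property, as in real anatomy), then per-subject stable
#' effects and per-session noise that shift the location of each region's
#' vertex distribution without changing its shape. The true reliability
#' ratio sigma_subject^2 / (sigma_subject^2 + sigma_session^2) and all
#' drawn means are recorded as ground truth.
#'
#' @param config a [simulation_config()].
#' @param atlas a region table; defaults to [make_default_atlas()].
#' @return A `morph_cohort` list with elements
#'   \describe{
#'     \item{features}{`features[[subject]][[session]]`: numeric matrix
#'       (vertices x regions, columns in atlas row order, named by region).}
#'     \item{subjects}{data frame with `subject`, `group`, `age`, `sex`.}
#'     \item{atlas}{the region table used.}
#'     \item{truth}{ground-truth record: `mu` (control region means),
#'       `mu_patient`, `reliability_ratio`, `group_effect`.}
#'     \item{config}{the configuration.}
#'   }
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_subjects = 3, seed = 7),
#'                           make_default_atlas(2, 2, 0))
#' dim(cohort$features[[1]][[1]])
simulate_cohort <- function(config, atlas = make_default_atlas()) {
  stopifnot(inherits(config, "morph_sim_config"))
  atlas <- validate_region_table(atlas)
  n_reg <- nrow(atlas)
  cls <- atlas$region_class
  with_seed(config$seed, {
    class_mu <- c(gyral = config$mu_gyral, sulcal = config$mu_sulcal,
                  ambiguous = (config$mu_gyral + config$mu_sulcal) / 2)
    class_tau <- c(gyral = config$tau_gyral, sulcal = config$tau_sulcal,
                   ambiguous = (config$tau_gyral + config$tau_sulcal) / 2)
    mu <- class_mu[cls] + stats::rnorm(n_reg, 0, class_tau[cls])
    names(mu) <- atlas$name
    sigma_r <- config$sigma_within *
      exp(stats::rnorm(n_reg, 0, config$sigma_within_cv))
    names(sigma_r) <- atlas$name
    # cohort-level perturbation of sulcal means in the patient group
    mu_patient <- mu
    sulcal <- cls == "sulcal"
    if (any(sulcal)) {
      # always drawn so the RNG stream does not depend on group_effect:
      # under a shared seed the perturbation scales linearly with it
      mu_patient[sulcal] <- mu[sulcal] +
        stats::rnorm(sum(sulcal), 0, config$group_effect)
    }
    group <- rep(c("patient", "control"),
                 c(config$n_patients, config$n_subjects - config$n_patients))
    subjects <- data.frame(
      subject = sprintf("sub%03d", seq_len(config$n_subjects)),
      group = group,
      age = round(stats::rnorm(config$n_subjects, 40, 12) +
                    ifelse(group == "patient", config$group_age_shift, 0), 1),
      sex = stats::rbinom(config$n_subjects, 1, 0.5),
      stringsAsFactors = FALSE
    )
    features <- vector("list", config$n_subjects)
    names(features) <- subjects$subject
    nv <- config$vertices_per_region
    for (s in seq_len(config$n_subjects)) {
      mu_s <- if (group[s] == "patient") mu_patient else mu
      delta <- stats::rnorm(n_reg, 0, config$sigma_subject)
      # the vertex-wise pattern is the subject's anatomy: drawn once per
      # subject and carried across sessions, which only shift its location
      base <- matrix(stats::rnorm(nv * n_reg, 0,
                                  rep(sigma_r, each = nv)),
                     nrow = nv, ncol = n_reg,
                     dimnames = list(NULL, atlas$name))
      sessions <- vector("list", config$n_sessions)
      names(sessions) <- sprintf("ses%d", seq_len(config$n_sessions))
      for (t in seq_len(config$n_sessions)) {
        eps <- stats::rnorm(n_reg, 0, config$sigma_session)
        sessions[[t]] <- base + rep(mu_s + delta + eps, each = nv)
      }
      features[[s]] <- sessions
    }
    denom <- config$sigma_subject^2 + config$sigma_session^2
    structure(list(
      features = features,
      subjects = subjects,
      atlas = atlas,
      truth = list(mu = mu, mu_patient = mu_patient, sigma_r = sigma_r,
                   reliability_ratio = if (denom > 0)
                     config$sigma_subject^2 / denom else NA_real_,
                   group_effect = config$group_effect),
      config = config
    ), class = "morph_cohort")
  })
}

#' Repair a similarity matrix to positive semidefiniteness
#'
#' Finite-sample between-subject correlation matrices can be indefinite.
#' Negative eigenvalues are clipped to zero and the diagonal renormalized
#' to 1 so the matrix is a valid covariance kernel for behaviour
#' generation.
#'
#' @param M symmetric matrix with unit diagonal.
#' @return PSD matrix with unit diagonal.
#' @export
psd_repair <- function(M) {
  if (!isSymmetric(unname(M), tol = 1e-8)) stop("M must be symmetric")
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  M2 <- eig$vectors %*% (vals * t(eig$vectors))
  d <- sqrt(pmax(diag(M2), .Machine$double.eps))
  M2 <- M2 / tcrossprod(d)
  diag(M2) <- 1
  (M2 + t(M2)) / 2
}

#' Simulate behaviour under the variance-component model
#'
#' Each item column is drawn from Y = B + E with B ~ N(0, sigma_b^2 M) and
#' E ~ N(0, sigma_e^2 I), where sigma_b^2 = `V_true` and sigma_e^2 =
#' 1 - `V_true`, so the true fraction of variance attributable to network
#' similarity is exactly `V_true`.
#'
#' @param M subject-by-subject similarity matrix (symmetric, unit
#'   diagonal); repaired to PSD internally.
#' @param n_items number of item columns to draw.
#' @param V_true true variance explained, in \[0, 1\].
#' @param seed RNG seed.
#' @return Numeric matrix (subjects x items) with attribute `V_true`.
#' @export
simulate_behavior <- function(M, n_items, V_true, seed = NULL) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("M must be a square matrix")
  if (V_true < 0 || V_true > 1) stop("V_true must be in [0, 1]")
  n <- nrow(M)
  Mp <- psd_repair(M)
  eig <- eigen(Mp, symmetric = TRUE)
  L <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), n)
  Y <- with_seed(seed, {
    B <- L %*% matrix(stats::rnorm(n * n_items), n, n_items) * sqrt(V_true)
    E <- matrix(stats::rnorm(n * n_items), n, n_items) * sqrt(1 - V_true)
    B + E
  })
  colnames(Y) <- sprintf("item%02d", seq_len(n_items))
  rownames(Y) <- rownames(M)
  attr(Y, "V_true") <- V_true
  Y
}
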