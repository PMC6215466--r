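# Synthetic cohorts with planted areal/system structure.
#
# Each subject's vertex time series is a sum of a band-limited system
# latent, a band-limited parcel latent, and white vertex noise, so that
# within-parcel correlation > within-system correlation > between-system
# correlation by construction.  Aging-like degradation enters through two
# knobs: `jitter_mm` (subject-specific blurring/displacement of planted
# parcel borders, spatially modulated by a smooth "vulnerability" field
# that also drives the anatomical deformation map) and
# `between_system_coupling` (shared variance mixed into the system
# latents, lowering system segregation).  Motion is a smooth random walk
# with Poisson spikes that also inject transient artifact into the series,
# giving scrubbing a measurable denoising effect.

#' Cohort specification
#'
#' @param name cohort label.
#' @param age_range numeric length-2, years.
#' @param n_subjects number of subjects (>= 1).
#' @param frames frames per subject (>= 80).
#' @param tr repetition time, seconds.
#' @param jitter_mm border displacement scale (0 = planted borders exact).
#' @param between_system_coupling fraction of shared variance mixed into
#'   system latents, in `[0, 1)`.
#' @param noise_sd white vertex noise SD (latents have unit SD).
#' @param motion_spike_rate expected motion spikes per frame.
#' @param seed integer seed; everything downstream is deterministic in it.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(name, age_range, n_subjects, frames = 200, tr = 2,
                        jitter_mm = 0, between_system_coupling = 0.1,
                        noise_sd = 1, motion_spike_rate = 0.03, seed = 1L) {
  if (n_subjects < 1) stopf("n_subjects must be >= 1")
  if (frames < 80) stopf("frames must be >= 80")
  if (between_system_coupling < 0 || between_system_coupling >= 1)
    stopf("between_system_coupling must be in [0, 1)")
  spec <- list(name = name, age_range = age_range, n_subjects = n_subjects,
               frames = frames, tr = tr, jitter_mm = jitter_mm,
               between_system_coupling = between_system_coupling,
               noise_sd = noise_sd, motion_spike_rate = motion_spike_rate,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

# Band-limited unit-variance latent signals, one per row.
band_limited_latents <- function(n, frames, tr, low = 0.009, high = 0.08) {
  x <- matrix(rnorm(n * frames), n, frames)
  x <- bandpass(x, tr_s = tr, low_hz = low, high_hz = high)
  sds <- apply(x, 1, sd)
  x / pmax(sds, 1e-12)
}

smooth_field <- function(mesh, fwhm = 15) {
  f <- rnorm(n_vertices(mesh))
  f <- smooth_map(mesh, f, fwhm)
  v <- f[!mesh$medial_wall]
  f <- (f - mean(v)) / sd(v)
  f[mesh$medial_wall] <- 0
  f
}

#' Simulate a cohort of subjects on a planted parcellation
#'
#' @param mesh a `surface_mesh`.
#' @param truth a `ground_truth` from [plant_parcellation()].
#' @param spec a [cohort_spec()].
#' @return list of `subject_data`: each has `timeseries` (V x frames),
#'   `motion` (frames x 6: tx, ty, tz mm, rx, ry, rz radians), `thickness`
#'   (mm), `deformation`, `task_betas` (V x 4 conditions), `age`,
#'   `effective_labels` (the subject's jittered parcel labels) and
#'   `spike_frames` (planted motion spikes, for verification).
#' @export
simulate_cohort <- function(mesh, truth, spec) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "ground_truth"))
  if (spec$frames < 80) stopf("frames must be >= 80")
  V <- n_vertices(mesh)
  valid <- !mesh$medial_wall
  n_parc <- length(truth$seed_vertices)
  n_sys <- length(truth$system_type)
  is_assoc_parcel <- truth$system_type[truth$system_of_parcel] == "association"

  # geodesic margins to the second-nearest planted seed (border proximity)
  dmat <- geodesic_distances(mesh, truth$seed_vertices)
  ord <- apply(dmat, 2, function(col) order(col)[1:2])
  d1 <- dmat[cbind(ord[1, ], seq_len(V))]
  d2 <- dmat[cbind(ord[2, ], seq_len(V))]
  margin <- d2 - d1
  second_label <- ord[2, ]

  # truth-level bases shared by every cohort simulated on this truth:
  # thickness baselines, task amplitudes, and each parcel's connectivity
  # fingerprint (loadings onto 8 shared latents, giving every parcel a
  # unique long-range RSFC profile -- the feature boundary mapping detects)
  bases <- local_seed(child_seed(truth$seed, 900L), {
    list(thickness_base = rnorm(n_parc, 2.5, 0.2),
         beta_amp = matrix(rnorm(n_parc * 4), n_parc, 4),
         fp_load = matrix(rnorm(n_parc * 8, 0, 0.3), n_parc, 8))
  })
  g_cohort <- local_seed(child_seed(spec$seed, 990L), smooth_field(mesh))

  lapply(seq_len(spec$n_subjects), function(i) {
    local_seed(child_seed(spec$seed, i), {
      Tn <- spec$frames
      age <- runif(1, spec$age_range[1], spec$age_range[2])
      g_mix <- 0.7 * g_cohort + 0.3 * smooth_field(mesh)
      vuln <- pmax(0, 1 + 0.8 * g_mix)

      eff <- truth$labels
      if (spec$jitter_mm > 0) {
        p <- 0.5 * exp(-margin / spec$jitter_mm) * vuln *
          (1 + 0.5 * as.numeric(is_assoc_parcel[pmax(truth$labels, 1)]))
        p[!valid | truth$labels == 0] <- 0
        flip <- runif(V) < pmin(p, 1)
        eff[flip] <- second_label[flip]
      }

      sys_lat <- band_limited_latents(n_sys, Tn, spec$tr)
      cc <- spec$between_system_coupling
      if (cc > 0 && n_sys > 1) {
        # pairwise heterogeneous coupling: each system's latent absorbs a
        # fraction cc of its variance from the *other systems' own*
        # latents, with random per-subject weights.  Unlike a single
        # shared global latent (which global-signal regression would
        # remove wholesale), heterogeneous pairwise mixing survives
        # nuisance cleaning, as between-system desegregation does in
        # practice.
        u <- matrix(runif(n_sys^2, 0.2, 1.8), n_sys, n_sys)
        mixed <- sqrt(1 - cc) * sys_lat
        for (i in seq_len(n_sys)) {
          b <- cc * u[i, -i] / sum(u[i, -i])
          mixed[i, ] <- mixed[i, ] +
            colSums(sqrt(b) * sys_lat[-i, , drop = FALSE])
        }
        sys_lat <- mixed
      }
      parc_lat <- band_limited_latents(n_parc, Tn, spec$tr)
      fp_lat <- band_limited_latents(ncol(bases$fp_load), Tn, spec$tr)

      ts <- matrix(rnorm(V * Tn, 0, spec$noise_sd), V, Tn)
      pos <- which(eff > 0)
      ts[pos, ] <- ts[pos, ] + parc_lat[eff[pos], , drop = FALSE] +
        sys_lat[truth$system_of_parcel[eff[pos]], , drop = FALSE] +
        (bases$fp_load %*% fp_lat)[eff[pos], , drop = FALSE]

      # motion: slow random walk, plus one-frame spikes that also inject
      # artifact into the series
      steps <- cbind(matrix(rnorm(Tn * 3, 0, 0.008), Tn, 3),
                     matrix(rnorm(Tn * 3, 0, 0.00016), Tn, 3))
      motion <- apply(steps, 2, cumsum)
      spikes <- which(runif(Tn) < spec$motion_spike_rate)
      spikes <- spikes[spikes > 1]
      if (length(spikes)) {
        motion[spikes, 1:3] <- motion[spikes, 1:3] + 0.1
        motion[spikes, 4:6] <- motion[spikes, 4:6] + 0.002
        ts[, spikes] <- ts[, spikes] +
          matrix(rnorm(V * length(spikes), 1.5, 1.5), V, length(spikes))
      }
      colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")

      thin_rate <- ifelse(is_assoc_parcel, 0.012, 0.004)
      thickness <- rep(NA_real_, V)
      lab_pos <- truth$labels > 0
      thickness[lab_pos] <- bases$thickness_base[truth$labels[lab_pos]] -
        thin_rate[truth$labels[lab_pos]] * (age - 20)
      thickness <- thickness + 0.05 * smooth_field(mesh)
      thickness[!valid] <- NA_real_

      deformation <- 1 + (spec$jitter_mm / 10) * vuln +
        0.02 * smooth_field(mesh)
      deformation[!valid] <- NA_real_

      task_betas <- bases$beta_amp[pmax(eff, 1), , drop = FALSE] +
        matrix(rnorm(V * 4, 0, 0.3), V, 4)
      task_betas[!valid | eff == 0, ] <- NA_real_

      subj <- list(timeseries = ts, motion = motion, thickness = thickness,
                   deformation = deformation, task_betas = task_betas,
                   age = age, effective_labels = eff, spike_frames = spikes,
                   cohort = spec$name)
      class(subj) <- "subject_data"
      subj
    })
  })
}
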