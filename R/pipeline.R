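# End-to-end orchestration: simulate cohorts -> preprocess -> cohort
# boundary maps -> parcellations -> cross-cohort evaluation -> network
# community detection, system matching and segregation -> age trends.
# Every stage is seeded from the study seed, so a rerun with the same
# configuration reproduces all outputs exactly.

#' Default study configuration
#'
#' Five age cohorts spanning 20-93 years with border jitter and
#' between-system coupling increasing across cohorts (the generator's
#' aging model), on an icosphere with planted parcels and systems.
#' `scale = "desk"` matches the package's reference desk scale (2562
#' vertices, 40 parcels, 5 systems, 20 subjects, 200 frames, 100
#' bootstraps); `scale = "mini"` is a reduced configuration for fast
#' exploratory runs and repeated-seed experiments.
#'
#' @param seed integer study seed.
#' @param scale `"desk"` or `"mini"`.
#' @param n_cohorts number of cohorts (2 to 5, default 5); cohorts are
#'   taken from the young end.
#' @param cohort_indices optional explicit cohort selection (indices into
#'   the YA/ME/ML/OE/OL ladder), overriding `n_cohorts`; the first index
#'   is the reference ("young") cohort.
#' @return nested configuration list.
#' @export
default_study_config <- function(seed = 1L, scale = c("desk", "mini"),
                                 n_cohorts = 5L, cohort_indices = NULL) {
  scale <- match.arg(scale)
  desk <- scale == "desk"
  ages <- list(c(20, 34), c(35, 49), c(50, 64), c(65, 79), c(80, 93))
  names(ages) <- c("YA", "ME", "ML", "OE", "OL")
  jitter <- c(0, 2, 4, 6, 8)
  coupling <- c(0.10, 0.175, 0.25, 0.325, 0.40)
  n_cohorts <- max(2L, min(5L, n_cohorts))
  idx <- if (is.null(cohort_indices)) seq_len(n_cohorts)
         else as.integer(cohort_indices)
  # the reduced scale keeps the desk mesh's vertex spacing (3.8 mm) by
  # shrinking the sphere with the vertex count, so mm-scale parameters
  # (jitter, smoothing) act at the same resolution; the node-distance
  # exclusion shrinks with the sphere
  list(
    seed = as.integer(seed),
    mesh = list(subdivisions = if (desk) 4L else 3L,
                radius_mm = if (desk) 50 else 25,
                medial_cap_deg = 18),
    truth = list(n_parcels = if (desk) 40L else 24L, n_systems = 5L),
    cohorts = lapply(idx, function(i) list(
      name = names(ages)[i], age_range = ages[[i]],
      n_subjects = if (desk) 20L else 12L,
      frames = if (desk) 200L else 140L, tr = 2,
      jitter_mm = jitter[i], between_system_coupling = coupling[i],
      noise_sd = 1, motion_spike_rate = 0.03)),
    boundary = list(n_boot = if (desk) 100L else 16L, fwhm_mm = 6),
    parcellation = list(threshold_q = 0.35),
    evaluation = list(n_rot = if (desk) 100L else 50L, top_q = 0.25),
    # the density grid and minimum community size scale with node count:
    # the 3-10% range suits hundreds of nodes, not the reduced graphs
    network = list(densities = if (desk) density_grid()
                               else seq(0.10, 0.30, by = 0.05),
                   n_boot = if (desk) 50L else 20L,
                   exclusion_mm = if (desk) 20 else 10,
                   min_size = if (desk) 6L else 3L, n_restarts = 5L),
    preprocess = list(fd_threshold_mm = 0.3, pad = 1L, min_frames = 75L,
                      rot_radius_mm = 50, low_hz = 0.009, high_hz = 0.08)
  )
}

#' Run the boundary-mapping pipeline for one cohort
#'
#' Simulate (or take) subjects, preprocess, compute per-subject
#' connectivity, bootstrap-average similarity gradients, and derive the
#' cohort boundary map and parcellation.
#'
#' @param mesh a `surface_mesh`.
#' @param truth a `ground_truth`.
#' @param spec a `cohort_spec`.
#' @param config study configuration (see [default_study_config()]).
#' @param subjects optional pre-simulated subject list.
#' @return list: `spec`, `subjects`, `clean`, `zmaps` (usable subjects),
#'   `mean_zmap`, `grad`, `boundary`, `parcellation`, `ages`,
#'   `n_usable`.
#' @export
run_cohort_pipeline <- function(mesh, truth, spec, config, subjects = NULL) {
  pp <- config$preprocess
  if (is.null(subjects)) subjects <- simulate_cohort(mesh, truth, spec)
  clean <- preprocess_cohort(subjects, mesh, tr_s = spec$tr,
                             fd_threshold_mm = pp$fd_threshold_mm,
                             pad = pp$pad, min_frames = pp$min_frames,
                             rot_radius_mm = pp$rot_radius_mm,
                             low_hz = pp$low_hz, high_hz = pp$high_hz)
  usable <- vapply(clean, `[[`, logical(1), "usable")
  if (sum(usable) < 2) stopf("cohort %s: fewer than 2 usable subjects", spec$name)
  zmaps <- lapply(clean[usable], subject_connectivity, mesh = mesh)
  mean_zmap <- Reduce(`+`, zmaps) / length(zmaps)
  grad <- cohort_bootstrap_gradient(zmaps, mesh,
                                    n_boot = config$boundary$n_boot,
                                    fwhm_mm = config$boundary$fwhm_mm,
                                    seed = child_seed(spec$seed, 23L))
  bmap <- boundary_map(grad, mesh)
  parc <- parcellate(bmap, mesh, threshold_q = config$parcellation$threshold_q)
  list(spec = spec, subjects = subjects, clean = clean, usable = usable,
       zmaps = zmaps, mean_zmap = mean_zmap, grad = grad, boundary = bmap,
       parcellation = parc,
       ages = vapply(subjects, `[[`, numeric(1), "age"),
       n_usable = sum(usable))
}

# Majority planted system per node of a parcellation.
planted_node_systems <- function(parcellation, truth) {
  labels <- parcel_labels(parcellation)
  ids <- sort(unique(labels[labels > 0]))
  planted <- system_labels(truth$labels, truth$system_of_parcel)
  vapply(ids, function(k) {
    tb <- table(planted[labels == k & planted > 0])
    if (length(tb) == 0) return(NA_integer_)
    as.integer(names(tb)[which.max(tb)])
  }, integer(1))
}

#' Network stage for one cohort
#'
#' Builds per-subject parcel graphs, detects bootstrap modal communities
#' across the density grid, collapses them to a cross-density consensus,
#' matches consensus communities to the planted systems, and computes
#' per-subject overall system segregation.
#'
#' @param cohort output of [run_cohort_pipeline()].
#' @param mesh a `surface_mesh`.
#' @param truth a `ground_truth`.
#' @param config study configuration.
#' @param seed integer seed.
#' @return list: `graphs`, `consensus` (`system_partition`), `match`
#'   (from [match_systems()]), `node_reference`, `segregation`
#'   (per usable subject), `ages`.
#' @export
run_network_stage <- function(cohort, mesh, truth, config, seed = 1L) {
  net <- config$network
  graphs <- lapply(cohort$clean[cohort$usable], function(cl)
    build_graph(cohort$parcellation, cl, mesh, exclusion_mm = net$exclusion_mm))
  modal <- vapply(net$densities, function(d)
    bootstrap_mode_communities(graphs, d, n_boot = net$n_boot,
                               seed = child_seed(seed, round(d * 1e4)),
                               n_restarts = net$n_restarts),
    integer(nrow(graphs[[1]]$z)))
  cons <- cross_density_consensus(modal, net$densities, min_size = net$min_size)
  node_ref <- planted_node_systems(cohort$parcellation, truth)
  match <- match_systems(cons$consensus, node_ref, cohort$parcellation, mesh,
                         n_rot = config$evaluation$n_rot,
                         seed = child_seed(seed, 5L))
  seg <- vapply(graphs, function(g) {
    system_segregation(g$z, match$matched, excluded = g$excluded,
                       scope = "overall")$segregation
  }, numeric(1))
  list(graphs = graphs, consensus = cons, match = match,
       node_reference = node_ref, segregation = seg,
       ages = vapply(cohort$clean[cohort$usable], `[[`, numeric(1), "age"))
}

#' Run the full synthetic study
#'
#' Simulates every cohort in the configuration, runs the boundary-mapping
#' pipeline per cohort, compares every cohort's boundary map and
#' parcellation with the first (young) cohort's, evaluates cohort-specific
#' versus young-parcellation homogeneity and silhouette on each cohort's
#' data, runs the network stage, and assembles per-subject segregation
#' against age.  Cohorts are processed sequentially and the dense
#' intermediates (time series, per-subject connectivity, gradient
#' matrices) are released after each cohort, so the peak working set is
#' one cohort's, not the study's.
#'
#' @param config configuration from [default_study_config()].
#' @param network run the network stage (default TRUE).
#' @param quality run the homogeneity/silhouette quality stage (default
#'   TRUE).
#' @return nested list with `mesh`, `truth`, `cohorts` (light per-cohort
#'   outputs: `boundary`, `parcellation`, `ages`, `n_usable`,
#'   `mean_thickness`, `mean_deformation`), `comparison` (per non-young
#'   cohort: dice, map_r, ari, overlap), `quality` (per cohort:
#'   homogeneity/silhouette for cohort-specific and young parcellations),
#'   `network` (per cohort), `age_trend`, `config`.
#' @export
run_study <- function(config = default_study_config(), network = TRUE,
                      quality = TRUE) {
  mesh <- make_sphere_mesh(config$mesh$subdivisions, config$mesh$radius_mm,
                           config$mesh$medial_cap_deg)
  truth <- plant_parcellation(mesh, config$truth$n_parcels,
                              config$truth$n_systems,
                              seed = child_seed(config$seed, 1L))
  ev <- config$evaluation
  cohorts <- list()
  qual <- list()
  net <- list()
  comparison <- list()
  young_boundary <- NULL
  young_parcellation <- NULL
  for (i in seq_along(config$cohorts)) {
    cc <- config$cohorts[[i]]
    sp <- cohort_spec(cc$name, cc$age_range, cc$n_subjects, cc$frames, cc$tr,
                      cc$jitter_mm, cc$between_system_coupling, cc$noise_sd,
                      cc$motion_spike_rate,
                      seed = child_seed(config$seed, 100L + i))
    co <- run_cohort_pipeline(mesh, truth, sp, config)
    if (i == 1) {
      young_boundary <- co$boundary
      young_parcellation <- co$parcellation
    } else {
      comparison[[cc$name]] <- list(
        dice = dice_boundary(young_boundary, co$boundary, ev$top_q),
        map_r = map_correlation(young_boundary, co$boundary),
        ari = adjusted_rand(young_parcellation, co$parcellation),
        overlap = match_parcels(co$parcellation,
                                young_parcellation)$mean_overlap)
    }
    if (quality) {
      sd_seed <- child_seed(config$seed, 300L + i)
      own_h <- homogeneity_z(co$parcellation, co$mean_zmap, mesh,
                             n_rot = ev$n_rot, seed = sd_seed)
      own_s <- silhouette_z(co$parcellation, co$mean_zmap, mesh,
                            n_rot = ev$n_rot, seed = sd_seed)
      young_h <- young_s <- NULL
      if (i > 1) {
        young_h <- homogeneity_z(young_parcellation, co$mean_zmap, mesh,
                                 n_rot = ev$n_rot, seed = sd_seed)
        young_s <- silhouette_z(young_parcellation, co$mean_zmap, mesh,
                                n_rot = ev$n_rot, seed = sd_seed)
      }
      qual[[cc$name]] <- list(own_homogeneity = own_h, own_silhouette = own_s,
                              young_homogeneity = young_h,
                              young_silhouette = young_s)
    }
    if (network) {
      net[[cc$name]] <- run_network_stage(co, mesh, truth, config,
                                          seed = child_seed(config$seed,
                                                            500L + i))
    }
    V <- n_vertices(mesh)
    cohorts[[cc$name]] <- list(
      spec = sp,
      boundary = co$boundary,
      parcellation = co$parcellation,
      ages = co$ages,
      n_usable = co$n_usable,
      mean_thickness = rowMeans(vapply(co$subjects, `[[`, numeric(V),
                                       "thickness")),
      mean_deformation = rowMeans(vapply(co$subjects, `[[`, numeric(V),
                                         "deformation")))
    rm(co)
    gc(verbose = FALSE)
  }
  age_trend <- NULL
  if (network) {
    seg <- unlist(lapply(net, `[[`, "segregation"))
    ages <- unlist(lapply(net, `[[`, "ages"))
    age_trend <- segregation_age_trend(seg, ages)
  }
  list(mesh = mesh, truth = truth, cohorts = cohorts,
       comparison = comparison, quality = if (quality) qual else NULL,
       network = if (network) net else NULL,
       age_trend = age_trend, config = config)
}
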