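# End-to-end BOF orchestration: simulate (or generate pure noise) -> pick by
# FLC (objective function A) -> threshold -> extract/phase-flip/bin/
# normalize -> verify by EM alignment (objective function B) -> evaluate.
# A scenario is the cross product of an SNR list and picking templates, each
# run with one or more EM starting references, all seeded deterministically
# from one master seed.

#' Scenario specification for a BOF experiment
#'
#' Defaults are "desk scale": a few 2048 x 2048 micrographs with 80
#' particles each at the full particle size (box 180, 1 A/pixel). Keeping
#' the particle, its box, and the particle density at the reference values
#' while shrinking only the field of view preserves the per-particle
#' detection SNR, so picking statistics remain comparable across scales;
#' the full scale (4096 x 4096, 323 particles) is reached by configuration.
#'
#' @param snr_list micrograph-level SNR values (empty vector: no cases).
#' @param picking_template subset of `"gaussian_circle"`,
#'   `"phantom_projection"`, `"decoy_projection"`.
#' @param mle_start subset of `"random_noise_image"`, `"gaussian_circle"`,
#'   `"unaligned_average"`.
#' @param K number of EM classes.
#' @param n_micrographs,n_particles,dims,box,pixel_size geometry.
#' @param threshold picks kept per micrograph (default `n_particles`).
#' @param n_views projection bank size.
#' @param ctf a [ctf_params()] object, or NULL to skip the CTF.
#' @param pure_noise simulate micrographs of pure Gaussian noise (no
#'   particles, no CTF); `snr_list` is ignored beyond providing one case.
#' @param run_em run the EM verification stage.
#' @param em_bin Fourier-crop binning factor before EM.
#' @param em_max_iter,em_tol,milestones EM controls.
#' @param grid transform grid for EM (default: rotations every 15 degrees,
#'   integer shifts within +/-2 at the binned scale).
#' @param pick_bin binning factor for the FLC pass (1 = off).
#' @param seed master seed.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(snr_list = 0.005,
                          picking_template = "gaussian_circle",
                          mle_start = "gaussian_circle",
                          K = 5, n_micrographs = 3, n_particles = 80,
                          dims = c(2048, 2048), box = 180, pixel_size = 1,
                          threshold = NULL, n_views = 6,
                          ctf = ctf_params(pixel_size = pixel_size),
                          pure_noise = FALSE, run_em = TRUE, em_bin = 3,
                          em_max_iter = 30, em_tol = 1e-7,
                          milestones = c(1, 10, 50, 100),
                          grid = transform_grid(n_rot = 24, t_max = 2),
                          pick_bin = 1, seed = 1) {
  tmpl_ok <- c("gaussian_circle", "phantom_projection", "decoy_projection")
  start_ok <- c("random_noise_image", "gaussian_circle", "unaligned_average")
  stopifnot(all(picking_template %in% tmpl_ok),
            all(mle_start %in% start_ok), K >= 1)
  structure(list(snr_list = snr_list, picking_template = picking_template,
                 mle_start = mle_start, K = K,
                 n_micrographs = n_micrographs, n_particles = n_particles,
                 dims = dims, box = box, pixel_size = pixel_size,
                 threshold = threshold %||% n_particles, n_views = n_views,
                 ctf = ctf, pure_noise = pure_noise, run_em = run_em,
                 em_bin = em_bin, em_max_iter = em_max_iter,
                 em_tol = em_tol, milestones = milestones, grid = grid,
                 pick_bin = pick_bin, seed = seed),
            class = "scenario_spec")
}

#' Particle bookkeeping for a scenario
#'
#' The stack size each case assembles: `n_micrographs * threshold`.
#'
#' @param scenario a [scenario_spec()].
#' @return integer particle count per case.
#' @export
scenario_particle_budget <- function(scenario) {
  as.integer(scenario$n_micrographs * scenario$threshold)
}

# Picking templates and reference projections shared by all cases of a
# scenario. Templates are rendered in the contrast of the data: with a CTF
# at underfocus the particles are dark, so structured templates (and the
# Gaussian circle) are negated to match.
scenario_assets <- function(scenario) {
  box <- scenario$box
  ps <- scenario$pixel_size
  contrast <- if (!is.null(scenario$ctf) && !scenario$pure_noise) -1 else 1
  bank <- NULL
  if (!scenario$pure_noise) {
    vol <- phantom_trimer(pixel_size = ps)
    bank <- render_projection_set(vol, n_views = scenario$n_views,
                                  rng_seed = derive_seed(scenario$seed, 9001),
                                  box = box, pixel_size = ps)
  }
  decoy_vol <- phantom_decoy(pixel_size = ps)
  decoy_proj <- render_projection_set(decoy_vol, n_views = 1,
                                      rng_seed = derive_seed(scenario$seed, 9002),
                                      box = box, pixel_size = ps)[[1]]
  # Structured templates for particle picking are filtered to 30 A; the
  # pure-noise control instead picks with a projection of the decoy at its
  # native ~11 A detail (the control emulates picking noise with a map-derived
  # template, whose replica must carry power through the 20-50 A band).
  cutoff <- if (scenario$pure_noise) 11 else 30
  templates <- list()
  for (tn in scenario$picking_template) {
    templates[[tn]] <- switch(tn,
      gaussian_circle = contrast * make_gaussian_circle(box, box / 18),
      phantom_projection = contrast *
        center_by_mass(lowpass_filter(bank[[1]], cutoff, pixel_size = ps)),
      decoy_projection = contrast *
        center_by_mass(lowpass_filter(decoy_proj, cutoff, pixel_size = ps)))
    attr(templates[[tn]], "pixel_size") <- ps
  }
  list(bank = bank, templates = templates, contrast = contrast)
}

# One (snr, template) case: simulate/pick/extract/evaluate and optionally
# verify with EM under each requested starting reference.
run_bof_case <- function(scenario, snr, template_name, assets, case_seed) {
  box <- scenario$box
  template <- assets$templates[[template_name]]
  n_keep <- scenario$threshold
  picks_all <- list()
  stacks <- list()
  matches <- list()
  dropoffs <- integer(0)
  for (i in seq_len(scenario$n_micrographs)) {
    seed_i <- derive_seed(case_seed, i)
    mic_id <- sprintf("mic%03d", i)
    if (scenario$pure_noise) {
      noisy <- with_seed(seed_i, matrix(stats::rnorm(prod(scenario$dims)),
                                        scenario$dims[1], scenario$dims[2]))
      attr(noisy, "pixel_size") <- scenario$pixel_size
      truth <- NULL
    } else {
      sim <- synthesize_micrograph(assets$bank, scenario$n_particles,
                                   scenario$dims, rng_seed = seed_i)
      noiseless <- sim$micrograph
      truth <- sim$truth
      if (!is.null(scenario$ctf)) noiseless <- apply_ctf(noiseless, scenario$ctf)
      noisy <- add_noise_to_snr(noiseless, snr,
                                rng_seed = derive_seed(seed_i, 7))
    }
    picks <- pick_particles(noisy, template,
                            n_max = max(2 * n_keep, n_keep + 50),
                            bin = scenario$pick_bin, micrograph_id = mic_id)
    dropoffs <- c(dropoffs, as.integer(dropoff_rank(picks$peak)))
    kept <- threshold_picks(picks, n_keep = n_keep)
    stacks[[i]] <- extract_particles(noisy, kept, box)
    picks_all[[i]] <- picks
    if (!is.null(truth)) {
      matches[[i]] <- match_picks(kept, truth, d_max = box / 4)
    }
  }
  stack <- NULL
  template_binned <- NULL
  if (scenario$run_em) {
    stack <- bind_stacks(stacks)
    if (!scenario$pure_noise && !is.null(scenario$ctf)) {
      stack <- phase_flip(stack, scenario$ctf)
    }
    stack <- bin_particles(stack, scenario$em_bin)
    stack <- normalize_particles(stack)
    template_binned <- bin_particles(array(template, c(box, box, 1)),
                                     scenario$em_bin)[, , 1]
    attr(template_binned, "pixel_size") <-
      scenario$pixel_size * scenario$em_bin
  }

  em <- list()
  if (scenario$run_em) {
    for (sm in scenario$mle_start) {
      start <- make_start_references(stack, mode = sm, K = scenario$K,
                                     rng_seed = derive_seed(case_seed, 501),
                                     t_max = max(scenario$grid$tx))
      fit <- em_align(stack, start, scenario$grid,
                      max_iter = scenario$em_max_iter, tol = scenario$em_tol,
                      milestones = scenario$milestones)
      frcs <- lapply(fit$model$A, function(a) {
        frc(template_binned, a,
            pixel_size = attr(template_binned, "pixel_size"))
      })
      em[[sm]] <- list(model = fit$model, trace = fit$trace,
                       start = start, posteriors = fit$posteriors,
                       frc_vs_template = frcs,
                       frc05_vs_template = vapply(frcs, frc_half_crossing,
                                                  numeric(1)))
    }
  }
  fp <- vapply(matches, function(m) m$fp_fraction, numeric(1))
  n_stack <- if (!is.null(stack)) {
    dim(stack)[3]
  } else {
    sum(vapply(stacks, function(s) dim(s)[3], integer(1)))
  }
  list(snr = snr, template = template_name,
       picks = do.call(rbind, picks_all),
       n_particles_stack = n_stack,
       stack = stack, template_binned = template_binned,
       matches = matches,
       fp_fractions = if (length(fp)) fp else numeric(0),
       fp_median = if (length(fp)) stats::median(fp) else NA_real_,
       dropoff_ranks = dropoffs,
       em = em)
}

bind_stacks <- function(stacks) {
  d <- dim(stacks[[1]])
  n <- sum(vapply(stacks, function(s) dim(s)[3], integer(1)))
  out <- array(0, c(d[1], d[2], n))
  coords <- list()
  at <- 0
  for (s in stacks) {
    k <- dim(s)[3]
    if (k) out[, , (at + 1):(at + k)] <- s
    coords[[length(coords) + 1]] <- attr(s, "coords")
    at <- at + k
  }
  attr(out, "pixel_size") <- attr(stacks[[1]], "pixel_size")
  attr(out, "coords") <- do.call(rbind, coords)
  out
}

#' Run a BOF scenario end to end
#'
#' Executes every (SNR, picking template) case of the scenario: simulation,
#' FLC picking, threshold selection, extraction, phase flipping, binning,
#' normalization, EM verification under each requested start, and the
#' evaluation readouts. A failure in one case is recorded in the manifest
#' and the remaining cases proceed. Re-running with the same scenario and
#' seed reproduces all numeric outputs.
#'
#' @param scenario a [scenario_spec()].
#' @param out_dir optional output directory; when given, pick tables (TSV),
#'   class averages (MRC), EM traces (TSV) and a JSON manifest are written.
#' @return list of class `bof_result`: `cases` (named list of case results)
#'   and `manifest` (summary list).
#' @export
run_bof <- function(scenario, out_dir = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  snrs <- if (scenario$pure_noise) NA_real_ else scenario$snr_list
  manifest <- list(seed = scenario$seed,
                   particle_budget_per_case = scenario_particle_budget(scenario),
                   cases = list())
  cases <- list()
  if (length(snrs) == 0) {
    if (!is.null(out_dir)) write_manifest(manifest, out_dir)
    return(structure(list(cases = cases, manifest = manifest),
                     class = "bof_result"))
  }
  assets <- scenario_assets(scenario)
  ci <- 0
  for (snr in snrs) {
    for (tn in scenario$picking_template) {
      ci <- ci + 1
      case_id <- if (scenario$pure_noise) {
        paste0("noise_", tn)
      } else {
        paste0("snr", snr, "_", tn)
      }
      bof_log("run_bof: case ", case_id)
      res <- tryCatch(
        run_bof_case(scenario, snr, tn, assets,
                     case_seed = derive_seed(scenario$seed, ci)),
        error = function(e) e)
      if (inherits(res, "error")) {
        manifest$cases[[case_id]] <- list(status = "error",
                                          message = conditionMessage(res))
        next
      }
      cases[[case_id]] <- res
      manifest$cases[[case_id]] <- list(
        status = "ok", snr = snr, template = tn,
        n_particles_stack = res$n_particles_stack,
        fp_median = res$fp_median,
        dropoff_ranks = res$dropoff_ranks,
        frc05_vs_template = lapply(res$em, `[[`, "frc05_vs_template"))
      if (!is.null(out_dir)) write_case_outputs(res, case_id, out_dir)
    }
  }
  if (!is.null(out_dir)) write_manifest(manifest, out_dir)
  structure(list(cases = cases, manifest = manifest, assets = assets),
            class = "bof_result")
}

write_case_outputs <- function(res, case_id, out_dir) {
  dir.create(file.path(out_dir, case_id), recursive = TRUE,
             showWarnings = FALSE)
  write_coords(file.path(out_dir, case_id, "picks.tsv"), res$picks)
  curve <- res$picks[order(res$picks$micrograph_id, res$picks$rank),
                     c("micrograph_id", "rank", "peak")]
  utils::write.table(curve, file.path(out_dir, case_id, "peak_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (sm in names(res$em)) {
    fit <- res$em[[sm]]
    avg <- array(unlist(fit$model$A),
                 c(dim(fit$model$A[[1]]), length(fit$model$A)))
    write_mrc(file.path(out_dir, case_id,
                        paste0("class_averages_", sm, ".mrc")),
              avg, pixel_size = fit$model$pixel_size)
    utils::write.table(as.data.frame(fit$trace),
                       file.path(out_dir, case_id, paste0("trace_", sm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
}

write_manifest <- function(manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
}
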