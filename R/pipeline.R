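#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end synthetic study — phantom geometry,
#' atlas-pool size, fusion parameters, test-retest design, stack emulation
#' and power parameters — with explicit seeds, so a run is reproducible from
#' its manifest. Serialises round-trip to YAML.
#'
#' @param output_dir directory for stage outputs and the manifest.
#' @param seed master integer seed; all stage seeds derive from it.
#' @param phantom named list of [phantom_spec()] arguments.
#' @param n_atlases atlas-pool size.
#' @param shape_variation_sd atlas shape variation SD (mm).
#' @param spacing acquisition voxel spacing (mm).
#' @param template_spacing template meshing spacing (mm).
#' @param fusion named list of [fusion_params()] arguments.
#' @param n_retest_subjects subjects in the test-retest arm.
#' @param jitter inter-study pose jitter (`trans_sd_mm`, `rot_sd_deg`).
#' @param stack 2D-stack emulation (`slice_thickness_mm`, `gap_mm`).
#' @param power power-map parameters (`delta_mm`, `alpha`, `p`).
#' @param stages character vector of stages to run, in order.
#' @return object of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1L,
                       phantom = list(), n_atlases = 4,
                       shape_variation_sd = 2,
                       spacing = c(2.5, 2.5, 2.5),
                       template_spacing = c(3, 3, 3),
                       fusion = list(),
                       n_retest_subjects = 3,
                       jitter = list(trans_sd_mm = 2, rot_sd_deg = 2),
                       stack = list(slice_thickness_mm = 8, gap_mm = 2),
                       power = list(delta_mm = 1, alpha = 0.05, p = 0.9),
                       stages = c("phantom", "segment", "thickness",
                                  "reliability", "power")) {
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 phantom = phantom, n_atlases = n_atlases,
                 shape_variation_sd = shape_variation_sd,
                 spacing = spacing, template_spacing = template_spacing,
                 fusion = fusion, n_retest_subjects = n_retest_subjects,
                 jitter = jitter, stack = stack, power = power,
                 stages = stages),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

draw_subject_specs <- function(base_spec, n, variation_sd, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      sp <- base_spec
      sp$endo_semiaxes <- pmax(6, base_spec$endo_semiaxes + rnorm(3, 0, variation_sd))
      sp$wall_thickness <- max(2, base_spec$wall_thickness +
                                 rnorm(1, 0, variation_sd / 2))
      sp$rng_seed <- sample.int(.Machine$integer.max - 1L, 1)
      sp
    })
  })
}

#' Run the end-to-end synthetic study
#'
#' Chains the requested stages — phantom/atlas generation, leave-one-out
#' segmentation accuracy, template thickness mapping of a test-retest
#' cohort in both a thin-slice (3D) and thick-slice (2D-stack) arm,
#' volumetric reliability statistics, and the per-point sample-size and
#' reduction maps — writing each stage's outputs plus a manifest with
#' parameter echo, seeds and file checksums. Deterministic stages rerun
#' bit-identically from the same config.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (also written to
#'   `output_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(dirname(config$output_dir)))
    stop("parent of output_dir does not exist: ", dirname(config$output_dir),
         call. = FALSE)
  dir.create(config$output_dir, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  manifest <- list(package_version = as.character(utils::packageVersion("cardiatlas")),
                   config = unclass(config), started_at = format(Sys.time()),
                   stages = list())
  base_spec <- do.call(phantom_spec, config$phantom)
  params <- do.call(fusion_params, config$fusion)
  pool <- NULL; template <- NULL
  th3 <- list(); th2 <- list()

  record <- function(stage, files, extra = list()) {
    files <- files[file.exists(files)]
    manifest$stages[[stage]] <<- c(list(
      files = as.list(setNames(as.character(tools::md5sum(files)), basename(files)))),
      extra)
  }

  for (stage in config$stages) {
    if (stage == "phantom") {
      pool <- generate_atlas_pool(base_spec, config$n_atlases,
                                  config$shape_variation_sd,
                                  rng_seed = config$seed,
                                  spacing = config$spacing)
      files <- unlist(lapply(pool, function(a) {
        fi <- out(paste0(a$atlas_id, "_intensity.nii.gz"))
        fl <- out(paste0(a$atlas_id, "_labels.nii.gz"))
        fj <- out(paste0(a$atlas_id, "_landmarks.json"))
        write_volume(a$intensity, fi); write_volume(a$labels, fl)
        write_landmarks(a$landmarks, fj)
        c(fi, fl, fj)
      }))
      truth <- dplyr::bind_rows(lapply(pool, function(a)
        tibble::tibble(atlas_id = a$atlas_id,
                       cavity_volume_mm3 = a$truth$cavity_volume_mm3,
                       myocardium_volume_mm3 = a$truth$myocardium_volume_mm3)))
      ft <- out("ground_truth.csv")
      write.csv(truth, ft, row.names = FALSE)
      record("phantom", c(files, ft), list(n_atlases = length(pool)))
    } else if (stage == "segment") {
      if (is.null(pool)) stop("segment stage requires the phantom stage", call. = FALSE)
      acc <- leave_one_out_accuracy(pool, params)
      fa <- out("loo_accuracy.csv")
      write.csv(acc, fa, row.names = FALSE)
      record("segment", fa,
             list(mean_dice_myocardium = mean(acc$dice_myocardium)))
    } else if (stage == "thickness") {
      if (is.null(pool)) stop("thickness stage requires the phantom stage", call. = FALSE)
      template <- build_template(pool, template_spacing = config$template_spacing)
      subj <- draw_subject_specs(base_spec, config$n_retest_subjects,
                                 config$shape_variation_sd,
                                 seed = config$seed + 1L)
      files <- character()
      for (i in seq_along(subj)) {
        pair <- generate_retest_pair(subj[[i]], jitter = config$jitter,
                                     rng_seed = config$seed + 100L + i,
                                     spacing = config$spacing)
        for (arm in c("3D", "2D")) {
          maps <- lapply(c(1, 2), function(acq) {
            ph <- pair[[acq]]
            labs <- ph$labels
            if (arm == "2D")
              labs <- resample_to_stack(labs, config$stack$slice_thickness_mm,
                                        config$stack$gap_mm, kind = "labels")
            surf <- extract_surfaces(labs)
            reg <- register_template(template, surf$endo, surf$epi,
                                     target_landmarks = ph$landmarks)
            measure_thickness(reg$endo, reg$epi,
                              subject_id = paste0("subject_", i),
                              acquisition_id = paste0("acq", acq, "_", arm))
          })
          if (arm == "3D") th3[[i]] <- maps else th2[[i]] <- maps
          for (acq in c(1, 2)) {
            f <- out(sprintf("thickness_s%02d_%s_acq%d.csv", i, arm, acq))
            write_point_table(maps[[acq]]$values, f)
            files <- c(files, f)
          }
        }
      }
      record("thickness", files,
             list(template_points = template$P, n_subjects = length(subj)))
    } else if (stage == "reliability") {
      if (is.null(pool)) stop("reliability stage requires the phantom stage", call. = FALSE)
      subj <- draw_subject_specs(base_spec, config$n_retest_subjects,
                                 config$shape_variation_sd,
                                 seed = config$seed + 1L)
      vols <- dplyr::bind_rows(lapply(seq_along(subj), function(i) {
        pair <- generate_retest_pair(subj[[i]], jitter = config$jitter,
                                     rng_seed = config$seed + 100L + i,
                                     spacing = config$spacing)
        dplyr::bind_rows(lapply(c(1, 2), function(acq) {
          v <- compute_volumetry(pair[[acq]]$labels, body_surface_area_m2 = 1.8)
          v$subject <- i; v$occasion <- acq; v
        }))
      }))
      wide <- tidyr::pivot_wider(vols[, c("subject", "occasion", "lvedvi_ml_m2")],
                                 names_from = "occasion",
                                 values_from = "lvedvi_ml_m2",
                                 names_prefix = "occ")
      stats <- list(
        n_subjects = nrow(wide),
        bland_altman = as.list(glance(bland_altman(wide, occ1, occ2))))
      if (nrow(wide) >= 3)
        stats$icc_lvedvi <- as.list(glance(icc_absolute_agreement(wide[, c("occ1", "occ2")])))
      fr <- out("reliability.json")
      jsonlite::write_json(stats, fr, auto_unbox = TRUE, digits = NA)
      record("reliability", fr)
    } else if (stage == "power") {
      if (length(th3) == 0)
        stop("power stage requires the thickness stage", call. = FALSE)
      d3 <- do.call(rbind, lapply(th3, function(m) m[[1]]$values - m[[2]]$values))
      d2 <- do.call(rbind, lapply(th2, function(m) m[[1]]$values - m[[2]]$values))
      map3 <- sample_size_map(difference_field(d3, modality = "3D"),
                              config$power$delta_mm, config$power$alpha,
                              config$power$p)
      map2 <- sample_size_map(difference_field(d2, modality = "2D"),
                              config$power$delta_mm, config$power$alpha,
                              config$power$p)
      red <- percent_reduction(map2, map3)
      per_point <- dplyr::mutate(
        dplyr::rename(tidy(map3), variance_3d = "variance", n_3d = "n_raw"),
        n_2d = map2$n_raw, variance_2d = map2$variance, pct_reduction = red)
      fp <- out("power_map.csv")
      write.csv(per_point[, c("point_index", "variance_2d", "variance_3d",
                              "n_2d", "n_3d", "pct_reduction")], fp,
                row.names = FALSE)
      summ <- list(summary_3d = as.list(glance(map3)),
                   summary_2d = as.list(glance(map2)),
                   mean_pct_reduction = mean(red, na.rm = TRUE))
      fs <- out("power_summary.json")
      jsonlite::write_json(summ, fs, auto_unbox = TRUE, digits = NA)
      files <- c(fp, fs)
      if (!is.null(template)) {
        fply <- out("sample_size_3d.ply")
        write_ply(template$midwall, fply, scalars = map3$n_raw)
        files <- c(files, fply)
      }
      record("power", files, list(mean_pct_reduction = summ$mean_pct_reduction))
    } else {
      stop("unknown stage: ", stage, call. = FALSE)
    }
  }
  manifest$finished_at <- format(Sys.time())
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
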