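#' Write and read volumes as NIfTI
#'
#' Volumes travel as NIfTI-1 (gzipped) with the grid's voxel size in the
#' header; in-mask vectors are expanded onto the full grid (NA outside).
#'
#' @param x 3-D/4-D array, or in-mask vector/matrix (voxels x volumes) with
#'   \code{grid}.
#' @param path File path (\code{.nii} or \code{.nii.gz}).
#' @param grid A [volume_grid()] for in-mask input.
#' @return \code{read_volume} returns the image as an array with attribute
#'   \code{voxel_size_mm}.
#' @export
write_volume <- function(x, path, grid = NULL) {
  if (!is.array(x) || (!is.null(grid) && length(dim(x)) == 2L &&
                       nrow(x) == sum(grid$mask))) {
    if (is.null(grid)) stop("grid is required for in-mask input")
    x <- as.matrix(x)
    vols <- apply(x, 2, function(col) {
      a <- array(NA_real_, grid$dims); a[grid$mask] <- col; a
    })
    x <- array(vols, c(grid$dims, ncol(x)))
    if (dim(x)[4] == 1L) x <- array(x, grid$dims)
  }
  vs <- if (!is.null(grid)) grid$voxel_size_mm else 3
  img <- RNifti::asNifti(x, reference = list(pixdim = c(-1, rep(vs, 3), rep(1, 4))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- as.array(img)
  attr(out, "voxel_size_mm") <- RNifti::pixdim(img)[1]
  out
}

#' Pipeline configuration
#'
#' All knobs of a simulation-plus-analysis run, serializable to JSON; every
#' run writes its resolved configuration beside its outputs.
#'
#' @param n_subjects Cohort size.
#' @param seed Master seed fixing every stochastic choice.
#' @param grid_dims,voxel_size_mm Grid geometry.
#' @param amplitude,noise_sd,link_intercept,link_slope Pattern-model
#'   parameters (see [pattern_model()] and [link_affine()]).
#' @param speed_mean,speed_between_sd Behavioral cohort parameters.
#' @param radius_mm,cost,center Decoding parameters.
#' @param smooth_beta_fwhm,smooth_map_fwhm Smoothing FWHMs (mm) applied to
#'   betas before decoding and to accuracy maps before group statistics.
#' @param n_perm Permutations for group inference.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_subjects = 8, seed = 1,
                            grid_dims = c(24, 24, 18), voxel_size_mm = 3,
                            amplitude = c(visual = 0.35, movement = 0.35,
                                          context = 0.35, prep = 0.35),
                            noise_sd = 1, link_intercept = -0.98,
                            link_slope = 0.9,
                            speed_mean = c(rotation = 1.7, mirror = 2.4),
                            speed_between_sd = c(rotation = 0.22,
                                                 mirror = 0.22),
                            radius_mm = 9, cost = 1, center = TRUE,
                            smooth_beta_fwhm = 2, smooth_map_fwhm = 8,
                            n_perm = 500) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A \code{pipeline_config}.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config, list())
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (!is.null(names(cfg[[nm]])) && is.null(names(v)))
      names(v) <- names(cfg[[nm]])
    cfg[[nm]] <- v
  }
  missing <- setdiff(names(do.call(pipeline_config, list())), names(raw))
  if (length(missing) > 0)
    stop("config at ", path, " lacks fields: ", paste(missing, collapse = ", "))
  cfg
}

.model_from_config <- function(config) {
  grid <- volume_grid(config$grid_dims, config$voxel_size_mm)
  pattern_model(grid, amplitude = config$amplitude,
                noise_sd = config$noise_sd,
                link = link_affine(config$link_intercept, config$link_slope))
}

.manifest_append <- function(out_dir, stage, paths, seed) {
  mf <- file.path(out_dir, "manifest.tsv")
  rows <- data.frame(stage = stage, path = paths,
                     md5 = unname(tools::md5sum(paths)), seed = seed,
                     time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     stringsAsFactors = FALSE)
  utils::write.table(rows, mf, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !file.exists(mf), append = file.exists(mf))
  invisible(mf)
}

#' Simulate a cohort to disk
#'
#' Generates the cohort under the configuration's master seed and writes a
#' BIDS-like layout: per subject, an events table, a trial log and the beta
#' series (NIfTI 4-D plus a regressor-info table); cohort-level, a
#' participants table with the performance summaries, the resolved config
#' and a manifest.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, the output directory.
#' @export
pipeline_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  set.seed(config$seed)
  model <- .model_from_config(config)
  cohort <- sample_cohort(config$n_subjects, model,
                          speed_mean = config$speed_mean,
                          speed_between_sd = config$speed_between_sd)
  paths <- character(0)
  part <- list()
  for (sub in cohort) {
    sdir <- file.path(out_dir, sub$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    p1 <- file.path(sdir, "events.tsv"); write_events(sub$session, p1)
    p2 <- file.path(sdir, "trials.tsv"); write_trials(sub$trials, p2)
    p3 <- file.path(sdir, "betas.nii.gz")
    write_volume(sub$betas$coefficients, p3, model$grid)
    p4 <- file.path(sdir, "betas_info.tsv")
    utils::write.table(sub$betas$info, p4, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "n/a")
    paths <- c(paths, p1, p2, p3, p4)
    part[[length(part) + 1L]] <- data.frame(
      participant_id = sub$subject_id,
      mean_rotation_speed = sub$performance$mean_rotation_speed,
      mean_mirror_speed = sub$performance$mean_mirror_speed,
      abs_rotation_mirror_diff = sub$performance$abs_rotation_mirror_diff,
      rho_rotation = sub$rho[["rotation"]], rho_mirror = sub$rho[["mirror"]])
  }
  p5 <- file.path(out_dir, "participants.tsv")
  utils::write.table(do.call(rbind, part), p5, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p6 <- file.path(out_dir, "config.json"); write_config(config, p6)
  .manifest_append(out_dir, "simulate", c(paths, p5, p6), config$seed)
  invisible(out_dir)
}

.load_cohort <- function(out_dir, config) {
  grid <- volume_grid(config$grid_dims, config$voxel_size_mm)
  subs <- sort(list.dirs(out_dir, recursive = FALSE))
  subs <- subs[grepl("sub-", basename(subs))]
  if (length(subs) == 0L)
    stop("no subject directories under ", out_dir,
         "; run the simulate stage first")
  lapply(subs, function(sdir) {
    vol <- read_volume(file.path(sdir, "betas.nii.gz"))
    coef <- matrix(vol[rep(grid$mask, dim(vol)[4])],
                   ncol = dim(vol)[4])
    info <- utils::read.table(file.path(sdir, "betas_info.tsv"), sep = "\t",
                              header = TRUE, na.strings = "n/a",
                              stringsAsFactors = FALSE)
    trials <- read_trials(file.path(sdir, "trials.tsv"))
    perf <- summarize_performance(trials)
    structure(list(subject_id = basename(sdir), session = NULL,
                   trials = trials, performance = perf, rho = NULL,
                   betas = beta_series(grid, coef, info)),
              class = "subject_dataset")
  })
}

# Smooth every beta volume of a series (in-mask values, zero-filled
# outside for the convolution).
smooth_beta_series <- function(betas, fwhm_mm) {
  if (fwhm_mm <= 0) return(betas)
  grid <- betas$grid
  sm <- apply(betas$coefficients, 2, function(col) {
    a <- array(0, grid$dims); a[grid$mask] <- col
    smooth_volume(a, fwhm_mm, grid$voxel_size_mm)[grid$mask]
  })
  beta_series(grid, sm, betas$info)
}

#' Run analysis stages over a simulated cohort directory
#'
#' \code{decode}: per subject and analysis, smooths the betas, runs the
#' searchlight and writes accuracy-minus-chance maps. \code{group}: smooths
#' the accuracy maps, runs the TFCE permutation test per analysis (with the
#' rotation-mirror confound where the analysis uses it) and writes
#' statistic volumes and cluster tables. Stages are restartable and
#' deterministic given the config.
#'
#' @param stages Subset of \code{c("decode", "group")}, in order.
#' @param config A [pipeline_config()].
#' @param out_dir Directory produced by [pipeline_simulate()].
#' @param analyses Which decoding analyses to run.
#' @return Invisibly, the output directory.
#' @export
pipeline_run <- function(stages, config, out_dir,
                         analyses = analysis_names()) {
  stages <- match.arg(stages, c("decode", "group"), several.ok = TRUE)
  grid <- volume_grid(config$grid_dims, config$voxel_size_mm)
  if ("decode" %in% stages) {
    set.seed(config$seed + 1L)
    cohort <- .load_cohort(out_dir, config)
    spheres <- searchlight_spheres(grid, config$radius_mm)
    cfg <- decoding_config(config$radius_mm, config$cost, config$center)
    paths <- character(0)
    for (sub in cohort) {
      sub$betas <- smooth_beta_series(sub$betas, config$smooth_beta_fwhm)
      for (an in analyses) {
        am <- run_searchlight_decoding(sub, an, cfg, spheres)
        p <- file.path(out_dir, sub$subject_id,
                       paste0("accuracy_", an, ".nii.gz"))
        write_volume(matrix(am$values, ncol = 1), p, grid)
        paths <- c(paths, p)
      }
    }
    .manifest_append(out_dir, "decode", paths, config$seed + 1L)
  }
  if ("group" %in% stages) {
    set.seed(config$seed + 2L)
    part_path <- file.path(out_dir, "participants.tsv")
    if (!file.exists(part_path))
      stop("missing ", part_path, "; run the simulate stage first")
    part <- utils::read.table(part_path, sep = "\t", header = TRUE)
    gdir <- file.path(out_dir, "group")
    dir.create(gdir, showWarnings = FALSE)
    paths <- character(0)
    for (an in analyses) {
      files <- file.path(out_dir, part$participant_id,
                         paste0("accuracy_", an, ".nii.gz"))
      if (!all(file.exists(files)))
        stop("missing accuracy maps for ", an, "; run the decode stage first")
      maps <- t(vapply(files, function(f) {
        a <- read_volume(f)
        smooth_volume(replace(a, is.na(a), 0), config$smooth_map_fwhm,
                      config$voxel_size_mm)[grid$mask]
      }, numeric(sum(grid$mask))))
      confound <- if (an == "context_rot_mirror")
        part$abs_rotation_mirror_diff else NULL
      design <- group_design(nrow(maps), confound = confound,
                             tested = "intercept")
      gsm <- permutation_fwe(maps, design, grid, n_perm = config$n_perm)
      p1 <- file.path(gdir, paste0(an, "_t.nii.gz"))
      write_volume(matrix(gsm$t, ncol = 1), p1, grid)
      p2 <- file.path(gdir, paste0(an, "_pfwe.nii.gz"))
      write_volume(matrix(gsm$p_fwe, ncol = 1), p2, grid)
      p3 <- file.path(gdir, paste0(an, "_clusters.tsv"))
      results_table(gsm, path = p3)
      paths <- c(paths, p1, p2, p3)
    }
    .manifest_append(out_dir, "group", paths, config$seed + 2L)
  }
  invisible(out_dir)
}
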