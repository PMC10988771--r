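#' Pipeline stage runners and command-line surface
#'
#' Each runner consumes a fixture/working directory in the package's file
#' formats and writes its stage outputs back into it. Every CSV output
#' starts with a comment header recording the RNG seed and a config digest
#' so stochastic stages can be replayed; read them with
#' `read.csv(..., comment.char = "#")`.
#'
#' @param out_dir Working directory.
#' @param cfg A [glio_config()]; defaults to `config.yaml` in `out_dir` if
#'   present.
#' @return The directory (invisibly), after writing stage outputs.
#' @name glio-pipeline
NULL

stamp_csv <- function(df, path, cfg) {
  con <- file(path, "w")
  writeLines(sprintf("# gliocircuit seed=%d config=%s", cfg$rng_seed,
                     config_hash(cfg)), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

dir_cfg <- function(out_dir, cfg) {
  if (!is.null(cfg)) return(cfg)
  p <- file.path(out_dir, "config.yaml")
  if (file.exists(p)) read_config(p) else glio_config()
}

#' @rdname glio-pipeline
#' @export
run_simulate <- function(out_dir, cfg = NULL) {
  cfg <- if (is.null(cfg)) glio_config(n_rotations = 1000, n_spins = 300) else cfg
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(cfg, file.path(out_dir, "config.yaml"))
  seed <- cfg$rng_seed

  es <- ecog_sim_spec(trial_plan = tibble(condition = c("rest", "easy", "hard"),
                                          duration_s = c(30, 10, 10),
                                          repeats = c(1L, 3L, 3L)),
                      easy_factor = 1.5, hard_factor = 2,
                      rng_seed = seed)
  sim <- simulate_ecog(es)
  write_ecog(sim$recording, file.path(out_dir, "ecog.txt"),
             file.path(out_dir, "ecog_markers.csv"))
  stamp_csv(sim$ground_truth, file.path(out_dir, "gt_ecog.csv"), cfg)

  bs <- bold_sim_spec(coupling = c(0.8, rep(0, 6)), rng_seed = seed + 1L)
  bold <- simulate_bold(bs)
  write_volume(bold$bold, file.path(out_dir, "bold.nii.gz"))
  write_volume(bold$masks$parenchyma, file.path(out_dir, "mask_parenchyma.nii.gz"))
  write_volume(bold$masks$tumour, file.path(out_dir, "mask_tumour.nii.gz"))
  write_volume(bold$masks$network, file.path(out_dir, "mask_network.nii.gz"))
  stamp_csv(bold$ground_truth, file.path(out_dir, "gt_bold.csv"), cfg)

  # electrode strip near the tumour, nominal 10 mm spacing, slightly off
  # voxel centres so snapping has work to do
  ctr <- voxel_to_world(bold$bold$affine, matrix(bs$tumour_centre - 1, 1))
  elec <- tibble(electrode_id = sprintf("S1E%d", 1:4), strip_id = "S1",
                 x_mm = ctr[1] + 0.3, y_mm = ctr[2] + 10 * (0:3) + 0.2,
                 z_mm = ctr[3] - 0.1)
  stamp_csv(elec, file.path(out_dir, "electrodes.csv"), cfg)

  mesh <- make_icosphere(3)
  labels <- make_parcellation(mesh, 7, rng_seed = seed + 2L)
  write_surface(mesh, file.path(out_dir, "mesh.csv"),
                labels = labels, labels_path = file.path(out_dir, "labels.csv"))

  cohort <- simulate_cohort(cohort_sim_spec(n_patients = 40,
                                            coefs = c(conn = 0.8, preop = 0.3),
                                            residual_sd = 0.5,
                                            rng_seed = seed + 3L))
  stamp_csv(cohort, file.path(out_dir, "cohort.csv"), cfg)
  feats <- simulate_electrode_features(slope = 2, rng_seed = seed + 4L)
  stamp_csv(feats, file.path(out_dir, "features.csv"), cfg)
  invisible(out_dir)
}

#' @rdname glio-pipeline
#' @export
run_ecog <- function(out_dir, cfg = NULL) {
  cfg <- dir_cfg(out_dir, cfg)
  rec <- read_ecog(file.path(out_dir, "ecog.txt"),
                   file.path(out_dir, "ecog_markers.csv"))
  res <- run_band_analysis(rec, cfg)
  stamp_csv(tidy(res), file.path(out_dir, "ecog_results.csv"), cfg)
  invisible(out_dir)
}

# world-space embedding of the unit sphere inside the volume grid
embedded_sphere_coords <- function(mesh, vol) {
  g <- dim(vol$data)[1:3]
  ctr <- voxel_to_world(vol$affine, matrix((g - 1) / 2, 1))
  sp <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  radius <- 0.35 * min(g * sp)
  sweep(mesh$vertices * radius, 2, as.numeric(ctr), "+")
}

#' @rdname glio-pipeline
#' @export
run_fc <- function(out_dir, cfg = NULL) {
  cfg <- dir_cfg(out_dir, cfg)
  bold <- read_volume(file.path(out_dir, "bold.nii.gz"), rank = 4)
  paren <- read_volume(file.path(out_dir, "mask_parenchyma.nii.gz"), rank = 3)
  tum <- read_volume(file.path(out_dir, "mask_tumour.nii.gz"), rank = 3)
  netv <- read_volume(file.path(out_dir, "mask_network.nii.gz"), rank = 3)
  elec <- utils::read.csv(file.path(out_dir, "electrodes.csv"),
                          comment.char = "#")
  mesh <- read_surface(file.path(out_dir, "mesh.csv"))$mesh
  vcoords <- embedded_sphere_coords(mesh, bold)
  snap_mask <- glio_volume((paren$data != 0) * 1, paren$affine)
  snapped <- list()
  for (i in seq_len(nrow(elec))) {
    sn <- snap_electrode_to_cortex(as.numeric(elec[i, c("x_mm", "y_mm", "z_mm")]),
                                   snap_mask, neighbours_mm = snapped)
    snapped[[length(snapped) + 1]] <- sn$world
    seed_sp <- make_seed(sn$world, cfg$seed_radius_mm, paren)
    cmap <- seed_fc_map(bold, seed_sp, paren, cfg$smooth_fwhm_mm)
    zvol <- glio_volume(ifelse(is.na(cmap$z), 0, cmap$z), cmap$affine)
    write_volume(zvol, file.path(out_dir, sprintf("fc_%s.nii.gz",
                                                  elec$electrode_id[i])))
    smap <- volume_to_surface(cmap, vcoords)
    write_surface_map(smap, file.path(out_dir, sprintf("fc_%s_surface.csv",
                                                       elec$electrode_id[i])))
  }
  net1 <- glio_volume((netv$data == 1) * 1, netv$affine)
  tn <- tumour_network_connectivity(bold, tum, net1, cfg$alpha_level)
  stamp_csv(glance(tn), file.path(out_dir, "tumour_network.csv"), cfg)
  invisible(out_dir)
}

#' @rdname glio-pipeline
#' @export
run_spin <- function(out_dir, cfg = NULL) {
  cfg <- dir_cfg(out_dir, cfg)
  srf <- read_surface(file.path(out_dir, "mesh.csv"),
                      file.path(out_dir, "labels.csv"))
  maps <- list.files(out_dir, "^fc_.*_surface\\.csv$", full.names = TRUE)
  if (!length(maps)) abort("no surface maps found; run the fc stage first",
                           class = "glio_argument_error")
  for (mp in maps) {
    smap <- read_surface_map(mp)
    res <- spin_test(smap, srf$labels, srf$mesh, cfg$n_spins,
                     rng_seed = cfg$rng_seed, alpha = cfg$alpha_level)
    stamp_csv(tidy(res),
              file.path(out_dir, sub("_surface\\.csv$", "_spin.csv",
                                     basename(mp))), cfg)
  }
  invisible(out_dir)
}

#' @rdname glio-pipeline
#' @export
run_assoc <- function(out_dir, cfg = NULL) {
  cfg <- dir_cfg(out_dir, cfg)
  cohort <- as_tibble(utils::read.csv(file.path(out_dir, "cohort.csv"),
                                      comment.char = "#"))
  loc <- fit_location_model(cohort)
  stamp_csv(tidy(loc), file.path(out_dir, "assoc_location.csv"), cfg)
  out <- fit_outcome_model(cohort)
  stamp_csv(tidy(out), file.path(out_dir, "assoc_outcome.csv"), cfg)
  sens <- fit_outcome_model(cohort, sensitivity = TRUE)
  stamp_csv(tidy(sens), file.path(out_dir, "assoc_outcome_sensitivity.csv"), cfg)
  feats <- as_tibble(utils::read.csv(file.path(out_dir, "features.csv"),
                                     comment.char = "#"))
  grid <- fit_psc_fc_grid(feats)
  stamp_csv(tidy(grid), file.path(out_dir, "assoc_grid.csv"), cfg)
  invisible(out_dir)
}

#' Command-line entry point
#'
#' `glio_cli(c("simulate", "--out", "DIR"))` etc. Subcommands: `simulate`,
#' `ecog`, `fc`, `spin`, `assoc`. Options: `--config FILE`, `--out DIR`
#' (required), `--seed N`. A thin Rscript wrapper is installed at
#' `system.file("cli", "gliocircuit.R", package = "gliocircuit")`.
#'
#' @param args Character vector of command-line arguments.
#' @return 0 on success (invisibly).
#' @export
glio_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: gliocircuit simulate|ecog|fc|spin|assoc --out DIR [--config FILE] [--seed N]"
  if (!length(args)) abort(usage, class = "glio_argument_error")
  sub <- args[1]; args <- args[-1]
  opt <- list(out = NULL, config = NULL, seed = NULL)
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args))
      abort(usage, class = "glio_argument_error")
    opt[[key]] <- args[i + 1]; i <- i + 2
  }
  if (is.null(opt$out)) abort(usage, class = "glio_argument_error")
  cfg <- if (!is.null(opt$config)) read_config(opt$config)
         else if (file.exists(file.path(opt$out, "config.yaml")))
           read_config(file.path(opt$out, "config.yaml"))
         else if (sub == "simulate") glio_config(n_rotations = 1000, n_spins = 300)
         else glio_config()
  if (!is.null(opt$seed)) cfg$rng_seed <- as.integer(opt$seed)
  switch(sub,
         simulate = run_simulate(opt$out, cfg),
         ecog = run_ecog(opt$out, cfg),
         fc = run_fc(opt$out, cfg),
         spin = run_spin(opt$out, cfg),
         assoc = run_assoc(opt$out, cfg),
         abort(paste("unknown subcommand:", sub), class = "glio_argument_error"))
  invisible(0L)
}
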