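#' Pipeline configuration
#'
#' The full pipeline is driven by one structured config (a YAML file or the
#' equivalent named list): input phantoms and/or stack paths, the coarsening
#' methods with their voxel-length grids, material, load, solver options,
#' output directory and a master seed from which all randomness flows.
#'
#' @param path Path to a YAML config file.
#' @return The config as a named list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  fill_config_defaults(yaml::read_yaml(path))
}

fill_config_defaults <- function(config) {
  defaults <- list(
    seed = 1L,
    output_dir = "trabfe_out",
    material = list(e_tissue_gpa = 10, nu = 0.3),
    load = list(strain = 0.008),
    solver = list(type = "auto", tol = 1e-8),
    log_fit_dmax_um = 300,
    methods = list(H = c(72, 144, 216, 288),
                   FL = c(72, 144, 216, 288),
                   FS = c(72, 144, 216, 288),
                   FT = c(72, 144, 216, 288)),
    phantoms = list(),
    input_stacks = character()
  )
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

#' Validate a pipeline configuration
#'
#' Checks the structural rules that [run_pipeline()] relies on: known
#' methods, voxel-length grids on the right step (multiples of the slice
#' increment, twice that for the First-Third method), representable phantom
#' specs, material/load sanity and existing input paths. An empty result
#' means the config is runnable.
#'
#' @param config A config list or a path to a YAML file.
#' @param base_increment_um Base slice increment the d-grids are checked
#'   against (36 um by default).
#' @return A tibble with columns `field` and `issue`, one row per problem.
#' @export
validate_config <- function(config, base_increment_um = 36) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- fill_config_defaults(config)
  issues <- list()
  add <- function(field, issue)
    issues[[length(issues) + 1L]] <<- tibble::tibble(field = field,
                                                     issue = issue)
  known <- c("H", "FL", "FS", "FT")
  bad <- setdiff(names(config$methods), known)
  if (length(bad))
    add("methods", paste("unknown method(s):", paste(bad, collapse = ", ")))
  for (m in intersect(names(config$methods), known)) {
    ds <- config$methods[[m]]
    step <- if (m == "FT") 2 * base_increment_um else base_increment_um
    off <- ds[abs(ds / step - round(ds / step)) > 1e-9]
    if (length(off))
      add(paste0("methods.", m),
          sprintf("d values {%s} not multiples of the %s step of %g um",
                  paste(off, collapse = ", "), m, step))
    lo <- 2 * base_increment_um
    hi <- if (m == "H") 8 * base_increment_um else 30 * base_increment_um
    out_rng <- ds[ds < lo | ds > hi]
    if (length(out_rng))
      add(paste0("methods.", m),
          sprintf("d values {%s} outside the conventional range [%g, %g] um",
                  paste(out_rng, collapse = ", "), lo, hi))
  }
  kinds <- c("solid_block", "prism_column", "plate_lattice", "grf")
  for (i in seq_along(config$phantoms)) {
    ph <- config$phantoms[[i]]
    fld <- sprintf("phantoms[%d]", i)
    if (is.null(ph$kind) || !ph$kind %in% kinds) {
      add(fld, paste("unknown phantom kind:",
                     if (is.null(ph$kind)) "<missing>" else ph$kind))
      next
    }
    if (is.null(ph$shape) || length(ph$shape) != 3L || any(ph$shape < 1))
      add(fld, "shape must be three positive integers")
    if (ph$kind == "grf" &&
        (is.null(ph$target_bvtv) || ph$target_bvtv <= 0.02 ||
         ph$target_bvtv >= 0.6))
      add(fld, "grf phantom needs target_bvtv in (0.02, 0.6)")
    if (ph$kind == "prism_column" && is.null(ph$phi))
      add(fld, "prism_column phantom needs phi")
    if (ph$kind == "plate_lattice" &&
        (is.null(ph$thickness_px) || is.null(ph$period_px)))
      add(fld, "plate_lattice phantom needs thickness_px and period_px")
  }
  for (p in config$input_stacks)
    if (!dir.exists(p) && !file.exists(p))
      add("input_stacks", paste("path does not exist:", p))
  if (length(config$phantoms) == 0L && length(config$input_stacks) == 0L)
    add("input", "no phantoms and no input stacks configured")
  mt <- config$material
  if (is.null(mt$e_tissue_gpa) || mt$e_tissue_gpa <= 0)
    add("material.e_tissue_gpa", "tissue modulus must be positive")
  if (is.null(mt$nu) || mt$nu < 0 || mt$nu >= 0.5)
    add("material.nu", "Poisson ratio must lie in [0, 0.5)")
  st <- config$load$strain
  if (is.null(st) || st <= 0 || st >= 0.05)
    add("load.strain", "strain must lie in (0, 0.05)")
  if (!config$solver$type %in% c("auto", "direct", "cg"))
    add("solver.type", "solver type must be auto, direct or cg")
  if (length(issues) == 0L)
    return(tibble::tibble(field = character(), issue = character()))
  dplyr::bind_rows(issues)
}

build_phantom <- function(ph, master_seed, index) {
  shape <- as.integer(ph$shape)
  px <- ph$pixel_size %||% 36
  inc <- ph$slice_increment %||% 36
  switch(ph$kind,
    solid_block = make_solid_block(shape, px, inc),
    prism_column = make_prism_column(shape, ph$phi, px, inc),
    plate_lattice = make_plate_lattice(shape, ph$thickness_px, ph$period_px,
                                       px, inc),
    grf = make_grf_phantom(shape, ph$target_bvtv,
                           ph$correlation_length %||% 150,
                           seed = (master_seed + (ph$seed_offset %||% index))
                             %% .Machine$integer.max,
                           pixel_size = px, slice_increment = inc,
                           anisotropy = ph$anisotropy %||% 2),
    stop("unknown phantom kind: ", ph$kind, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full coarsening / micro-FE / regression pipeline
#'
#' Generates or loads the configured samples, builds the basic voxel model
#' of each, computes its structural indices, solves uniaxial compression on
#' the basic and every coarsened model, fits the logarithmic decay of the
#' relative modulus per (sample, method), and, when at least three samples
#' are available, regresses the absolute decay slopes on the structural
#' indices. All tables are written as CSV under the configured output
#' directory; a run is byte-reproducible for a fixed config and seed.
#'
#' @param config A config list or path to a YAML file (see
#'   [read_pipeline_config()]).
#' @param output_dir Optional override of the config's output directory.
#' @return Invisibly, a list with tibbles `indices`, `curves`, `fits`,
#'   `table2` (NULL when < 3 samples) and `counts` (per-stage element and
#'   node counts).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- fill_config_defaults(config)
  problems <- validate_config(config)
  if (nrow(problems) > 0L)
    stop("invalid config:\n",
         paste(sprintf("  %s: %s", problems$field, problems$issue),
               collapse = "\n"), call. = FALSE)
  out_dir <- output_dir %||% config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  mat <- material_props(config$material$e_tissue_gpa, config$material$nu)
  load <- load_case(config$load$strain)
  solver <- config$solver$type
  tol <- config$solver$tol

  stacks <- list()
  for (i in seq_along(config$phantoms)) {
    stacks[[sprintf("phantom_%02d", i)]] <-
      build_phantom(config$phantoms[[i]], config$seed, i)
  }
  for (p in config$input_stacks)
    stacks[[basename(p)]] <- read_stack(p)

  indices <- list(); curves <- list(); fits <- list(); counts <- list()
  for (sid in names(stacks)) {
    stack <- stacks[[sid]]
    basic <- build_basic_model(stack)
    idx <- compute_indices(basic)
    indices[[sid]] <- dplyr::bind_cols(tibble::tibble(sample_id = sid), idx)
    mesh0 <- voxels_to_elements(basic)
    mesh <- filter_connectivity(mesh0)
    res <- assemble_and_solve(mesh, mat, load, solver = solver, tol = tol)
    counts[[sid]] <- tibble::tibble(
      sample_id = sid, stage = "basic",
      slices = n_slices(stack), voxels = sum(basic$occupancy),
      elements_before = nrow(mesh0$elems), elements_after = nrow(mesh$elems),
      nodes = nrow(mesh$nodes))
    for (m in names(config$methods)) {
      crv <- relative_modulus_curve(stack, m, config$methods[[m]],
                                    mat, load, basic_e_app = res$e_app_gpa,
                                    solver = solver, tol = tol)
      curves[[paste(sid, m)]] <-
        dplyr::bind_cols(tibble::tibble(sample_id = sid),
                         tibble::as_tibble(crv))
      fit <- tryCatch(log_fit(crv$d_um, crv$re, config$log_fit_dmax_um),
                      error = function(e) NULL)
      if (!is.null(fit))
        fits[[paste(sid, m)]] <- tibble::tibble(
          sample_id = sid, method = m, form = fit$form,
          a = fit$a, b = fit$b, r2 = fit$r2, n = fit$n)
    }
  }
  indices <- dplyr::bind_rows(indices)
  curves <- dplyr::bind_rows(curves)
  fits <- dplyr::bind_rows(fits)
  counts <- dplyr::bind_rows(counts)
  table2 <- NULL
  if (nrow(indices) >= 3L && nrow(fits) > 0L) {
    joined <- dplyr::inner_join(fits, indices, by = "sample_id")
    table2 <- slope_index_table(
      joined, indices = c("bv_tv", "tb_th_mm", "tb_n_per_mm", "vm_mm3"))
  }
  utils::write.csv(indices, file.path(out_dir, "indices.csv"),
                   row.names = FALSE)
  utils::write.csv(curves, file.path(out_dir, "curves.csv"),
                   row.names = FALSE)
  utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
  if (!is.null(table2))
    utils::write.csv(table2, file.path(out_dir, "table2.csv"),
                     row.names = FALSE)
  utils::write.csv(counts, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  invisible(list(indices = indices, curves = curves, fits = fits,
                 table2 = table2, counts = counts))
}
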