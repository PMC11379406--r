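#' Analysis configuration
#'
#' Bundles everything one end-to-end run needs: exactly one input source
#' (paths to two channel volumes plus masks, or a [phantom_spec()]), the
#' symmetry plane for contralateral placement, and the region/histogram
#' parameters.  Defaults encode the canonical analysis choices: 1 mm
#' shells, a 1 mm band half-width (2 mm thick boundary band), and
#' 100 histogram bins.
#'
#' @param paths named list of input files (`channel_A`, `channel_B`,
#'   `tumor`, optional `brain`, optional `ventricles`), or `NULL` when
#'   generating a phantom.
#' @param phantom a [phantom_spec()] (or plain list of its arguments),
#'   or `NULL` when reading files.
#' @param symmetry_plane list `(axis, coordinate)` for
#'   [contralateral_region()]; defaults to the phantom mid-plane for
#'   phantom input and is required for file input.
#' @param shell_thickness_mm shell pitch (default 1 mm).
#' @param band_half_width_mm boundary-band half width (default 1 mm).
#' @param n_outward_shells outward shells to compute (default 5).
#' @param histogram_bins joint-histogram bins per axis (default 100).
#' @param output_dir where [run_analysis()] writes artifacts.
#' @param seed integer seed governing all randomness in the run.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(paths = NULL, phantom = NULL,
                            symmetry_plane = NULL,
                            shell_thickness_mm = 1.0,
                            band_half_width_mm = 1.0,
                            n_outward_shells = 5L,
                            histogram_bins = 100L,
                            output_dir = "cryocontrast_out",
                            seed = 1L) {
  if (is.null(paths) == is.null(phantom))
    stop("analysis_config: exactly one input source required (paths OR phantom)",
         call. = FALSE)
  if (!is.null(phantom) && !inherits(phantom, "phantom_spec")) {
    phantom$seed <- if (!is.null(phantom$seed)) phantom$seed else seed
    phantom <- do.call(phantom_spec,
                       phantom[intersect(names(phantom),
                                         names(formals(phantom_spec)))])
  }
  if (!is.null(paths)) {
    need <- c("channel_A", "channel_B", "tumor")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stop(sprintf("analysis_config: missing input path(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    for (nm in names(paths))
      if (!file.exists(paths[[nm]]) && !dir.exists(paths[[nm]]))
        stop(sprintf("analysis_config: input path for '%s' does not exist: %s",
                     nm, paths[[nm]]), call. = FALSE)
    if (is.null(symmetry_plane))
      stop("analysis_config: symmetry_plane (axis, coordinate) is required for file input",
           call. = FALSE)
  }
  for (p in c(shell_thickness_mm, band_half_width_mm))
    if (!is.numeric(p) || p <= 0)
      stop("analysis_config: all mm parameters must be > 0", call. = FALSE)
  if (histogram_bins < 1L || n_outward_shells < 1L)
    stop("analysis_config: histogram_bins and n_outward_shells must be >= 1",
         call. = FALSE)
  structure(list(paths = paths, phantom = phantom,
                 symmetry_plane = symmetry_plane,
                 shell_thickness_mm = shell_thickness_mm,
                 band_half_width_mm = band_half_width_mm,
                 n_outward_shells = as.integer(n_outward_shells),
                 histogram_bins = as.integer(histogram_bins),
                 output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file with the fields of [analysis_config()]; the
#'   phantom source is given as a `phantom:` mapping of
#'   [phantom_spec()] arguments.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(sprintf("config '%s': unknown field(s): %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  do.call(analysis_config, raw)
}

md5_of_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  yaml::write_yaml(x, tf)
  unname(tools::md5sum(tf))
}

#' Run the full contrast analysis
#'
#' Loads (or generates) the two channels and masks, builds every
#' analysis region, computes both TBR variants, both CNR variants,
#' shell profiles, joint histograms and both cross-correlations, and
#' writes a reproducible artifact set: `report.json`,
#' `profiles/*.csv`, `joint_histogram_{tumor,band}.csv` (+ JSON
#' sidecars), multi-label shell volumes, and `run.log`.  Given fixed
#' inputs and seed, `report.json` is byte-identical across runs.  Any
#' failure names the stage it occurred in and removes partial outputs.
#'
#' @param config an [analysis_config()].
#' @param output_dir overrides `config$output_dir` when given.
#' @return The contrast report (invisibly also written as JSON): a list
#'   with per-channel `tbr_whole`, `tbr_margin`, `cnr_whole`,
#'   `cnr_margin`, the `cross_correlation` of the two channels over the
#'   bulk tumor and the boundary band, and the region statistics of
#'   every region used.
#' @export
run_analysis <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  out_dir <- if (!is.null(output_dir)) output_dir else config$output_dir
  stage <- "setup"
  written <- character(0)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines[[length(log_lines) + 1L]] <<- sprintf(fmt, ...)
  }
  fail <- function(e) {
    unlink(written, recursive = TRUE, force = TRUE)
    stop(sprintf("run_analysis failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    stage <- "load inputs"
    if (!is.null(config$phantom)) {
      ph <- generate_phantom(config$phantom)
      vols <- list(channel_A = ph$channel_A, channel_B = ph$channel_B)
      tumor <- ph$tumor; brain <- ph$brain
      plane <- if (!is.null(config$symmetry_plane)) config$symmetry_plane
               else phantom_symmetry_plane(config$phantom)
      hashes <- list(phantom_spec = md5_of_object(unclass(config$phantom)))
      note("input: phantom (seed %d), spec md5 %s", config$phantom$seed,
           hashes$phantom_spec)
    } else {
      vols <- list(channel_A = read_volume(config$paths$channel_A),
                   channel_B = read_volume(config$paths$channel_B))
      tumor <- read_mask(config$paths$tumor, name = "tumor")
      brain <- if (!is.null(config$paths$brain))
        read_mask(config$paths$brain, name = "brain") else NULL
      plane <- config$symmetry_plane
      hashes <- lapply(config$paths, function(p)
        if (dir.exists(p)) md5_of_object(list.files(p)) else
          unname(tools::md5sum(p)))
      for (nm in names(config$paths))
        note("input: %s = %s (md5 %s)", nm, config$paths[[nm]], hashes[[nm]])
    }
    stage <- "grid check"
    all_objs <- c(vols, list(tumor = tumor))
    if (!is.null(brain)) all_objs$brain <- brain
    assert_coregistered(all_objs)

    stage <- "regions"
    inward <- inward_shells(tumor, config$shell_thickness_mm)
    outward <- outward_shells(tumor, config$shell_thickness_mm,
                              n_shells = config$n_outward_shells,
                              limit_mask = brain)
    margins <- margin_regions(tumor, limit_mask = brain,
                              thickness_mm = config$shell_thickness_mm)
    band <- boundary_band(tumor, config$band_half_width_mm,
                          limit_mask = brain)
    contra <- contralateral_region(tumor, plane$axis, plane$coordinate)
    regions <- list(tumor = tumor, contralateral = contra,
                    inner_1mm = margins$inner_1mm,
                    outer_1mm = margins$outer_1mm, band = band)
    for (nm in names(regions))
      note("region %s: %d voxels", nm, mask_count(regions[[nm]]))
    note("inward shells: %s voxels",
         paste(vapply(inward$shells, mask_count, numeric(1)), collapse = "/"))
    note("outward shells: %s voxels",
         paste(vapply(outward$shells, mask_count, numeric(1)), collapse = "/"))

    stage <- "metrics"
    chan_report <- list()
    for (ch in c("A", "B")) {
      v <- vols[[paste0("channel_", ch)]]
      chan_report[[ch]] <- list(
        tbr_whole = tbr_whole(v, tumor, contra),
        tbr_margin = tbr_margin(v, margins$inner_1mm, margins$outer_1mm),
        cnr_whole = cnr(v, tumor, contra),
        cnr_margin = cnr(v, margins$inner_1mm, margins$outer_1mm))
    }
    cc <- list(
      tumor = cross_correlation(vols$channel_A, vols$channel_B, tumor),
      band = cross_correlation(vols$channel_A, vols$channel_B, band))
    profiles <- lapply(c(A = "A", B = "B"), function(ch)
      shell_profile(vols[[paste0("channel_", ch)]], list(inward, outward),
                    channel = ch))
    jh_tumor <- joint_histogram(vols$channel_A, vols$channel_B, tumor,
                                n_bins = config$histogram_bins)
    jh_band <- joint_histogram(vols$channel_A, vols$channel_B, band,
                               n_bins = config$histogram_bins)

    stage <- "report"
    region_stats_out <- lapply(regions, function(m) {
      s <- region_stats(vols$channel_A, m)
      sB <- region_stats(vols$channel_B, m)
      list(n_voxels = s$n_voxels,
           mean_A = s$mean, sd_A = s$sd,
           mean_B = sB$mean, sd_B = sB$sd)
    })
    report <- list(
      channels = chan_report,
      cross_correlation = cc,
      regions = region_stats_out,
      parameters = list(shell_thickness_mm = config$shell_thickness_mm,
                        band_half_width_mm = config$band_half_width_mm,
                        n_outward_shells = config$n_outward_shells,
                        histogram_bins = config$histogram_bins,
                        seed = config$seed),
      input_hashes = hashes)

    stage <- "write artifacts"
    if (!dir.exists(out_dir)) {
      dir.create(out_dir, recursive = TRUE)
      written <- c(written, out_dir)
    }
    wfile <- function(p) { written <<- c(written, p); p }
    jsonlite::write_json(report, wfile(file.path(out_dir, "report.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    prof_dir <- file.path(out_dir, "profiles")
    if (!dir.exists(prof_dir)) dir.create(prof_dir)
    for (ch in names(profiles))
      utils::write.csv(
        data.frame(position_mm = profiles[[ch]]$positions,
                   value = profiles[[ch]]$values),
        wfile(file.path(prof_dir, sprintf("shell_profile_%s.csv", ch))),
        row.names = FALSE)
    write_jh <- function(jh, tag) {
      utils::write.table(jh$counts,
                         wfile(file.path(out_dir,
                                         sprintf("joint_histogram_%s.csv", tag))),
                         sep = ",", row.names = FALSE, col.names = FALSE)
      jsonlite::write_json(
        list(region = jh$region_name, n_bins = jh$n_bins,
             edges_A = jh$edges_A, edges_B = jh$edges_B,
             norm_params_A = jh$norm_params_A,
             norm_params_B = jh$norm_params_B),
        wfile(file.path(out_dir, sprintf("joint_histogram_%s.json", tag))),
        auto_unbox = TRUE, digits = NA)
    }
    write_jh(jh_tumor, "tumor")
    write_jh(jh_band, "band")
    write_shell_labels(inward,
                       wfile(file.path(out_dir, "shells_inward.nrrd")))
    if (length(outward$shells) > 0L)
      write_shell_labels(outward,
                         wfile(file.path(out_dir, "shells_outward.nrrd")))
    writeLines(log_lines, wfile(file.path(out_dir, "run.log")))
    invisible(report)
  }, error = fail)
}

# ---- command-line interface -------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: cryocontrast <subcommand> [options]",
    "",
    "subcommands:",
    "  generate-phantom  --out DIR [--config SPEC.yaml] [--seed N] [--format nrrd|nifti|tiff_stack]",
    "  analyze           --config CONFIG.yaml [--out DIR] [--seed N]",
    "  shells            --config CONFIG.yaml --out DIR [--format nrrd|nifti]",
    sep = "\n")
}

parse_cli_args <- function(argv) {
  opts <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (a %in% c("--config", "--seed", "--out", "--format")) {
      if (i == length(argv))
        stop(sprintf("flag %s needs a value", a), call. = FALSE)
      opts[[sub("^--", "", a)]] <- argv[i + 1L]
      i <- i + 2L
    } else {
      stop(sprintf("unknown flag '%s'", a), call. = FALSE)
    }
  }
  opts
}

#' Command-line entry point
#'
#' Thin shell over the package functions: `generate-phantom` writes the
#' two channels, three masks and the spec used; `analyze` runs
#' [run_analysis()] from a YAML config; `shells` exports the shell
#' label volumes only.  Returns (rather than calls `quit` with) the
#' exit code, so it is testable in-process: 0 on success, 2 on usage
#' errors, 1 on run failures.
#'
#' @param argv character vector of command-line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code.
#' @export
cryo_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L) {
    message(cli_usage())
    return(2L)
  }
  sub <- argv[1]
  if (!sub %in% c("generate-phantom", "analyze", "shells")) {
    message(sprintf("unknown subcommand '%s'\n%s", sub, cli_usage()))
    return(2L)
  }
  opts <- tryCatch(parse_cli_args(argv[-1]),
                   error = function(e) e)
  if (inherits(opts, "error")) {
    message(sprintf("%s\n%s", conditionMessage(opts), cli_usage()))
    return(2L)
  }
  tryCatch({
    switch(sub,
      "generate-phantom" = {
        if (is.null(opts$out))
          stop("generate-phantom: --out DIR is required", call. = FALSE)
        spec <- if (!is.null(opts$config)) read_phantom_spec(opts$config)
                else phantom_spec()
        if (!is.null(opts$seed)) spec$seed <- as.integer(opts$seed)
        fmt <- if (!is.null(opts$format)) opts$format else "nrrd"
        ext <- switch(fmt, nrrd = ".nrrd", nifti = ".nii.gz",
                      tiff_stack = "",
                      stop(sprintf("unsupported format '%s'", fmt),
                           call. = FALSE))
        if (!dir.exists(opts$out)) dir.create(opts$out, recursive = TRUE)
        ph <- generate_phantom(spec)
        write_volume(ph$channel_A,
                     file.path(opts$out, paste0("channel_A", ext)), fmt)
        write_volume(ph$channel_B,
                     file.path(opts$out, paste0("channel_B", ext)), fmt)
        for (nm in c("tumor", "brain", "ventricles"))
          write_mask(ph[[nm]], file.path(opts$out, paste0(nm, ext)), fmt)
        write_phantom_spec(spec, file.path(opts$out, "phantom_spec.yaml"))
        message(sprintf("phantom written to %s (seed %d)", opts$out,
                        spec$seed))
      },
      "analyze" = {
        if (is.null(opts$config))
          stop("analyze: --config CONFIG.yaml is required", call. = FALSE)
        config <- read_analysis_config(opts$config)
        if (!is.null(opts$seed)) {
          config$seed <- as.integer(opts$seed)
          if (!is.null(config$phantom))
            config$phantom$seed <- config$seed
        }
        out <- if (!is.null(opts$out)) opts$out else config$output_dir
        run_analysis(config, output_dir = out)
        message(sprintf("analysis complete; report at %s",
                        file.path(out, "report.json")))
      },
      "shells" = {
        if (is.null(opts$config) || is.null(opts$out))
          stop("shells: --config and --out are required", call. = FALSE)
        config <- read_analysis_config(opts$config)
        if (!is.null(config$phantom)) {
          tumor <- generate_phantom(config$phantom)$tumor
        } else {
          tumor <- read_mask(config$paths$tumor, name = "tumor")
        }
        fmt <- if (!is.null(opts$format)) opts$format else "nrrd"
        ext <- switch(fmt, nrrd = ".nrrd", nifti = ".nii.gz",
                      stop(sprintf("unsupported format '%s'", fmt),
                           call. = FALSE))
        if (!dir.exists(opts$out)) dir.create(opts$out, recursive = TRUE)
        inward <- inward_shells(tumor, config$shell_thickness_mm)
        write_shell_labels(inward,
                           file.path(opts$out, paste0("shells_inward", ext)),
                           fmt)
        message(sprintf("shell labels written to %s", opts$out))
      })
    0L
  }, error = function(e) {
    message(sprintf("error [%s]: %s", sub, conditionMessage(e)))
    1L
  })
}
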